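# target name        accession  query name           accession    E-value  score  bias
o01                  -          P_mcp                -            1e-12    55.2   0.0
o01                  -          P_polB               -            1e-10    40.1   0.0
o03                  -          P_mcp                -            1e-09    30.0   0.0
o04                  -          P_vltf3              -            1e-15    60.3   0.1
o06                  -          P_mcp                -            5e-11    44.0   0.0
o06                  -          P_mcp                -            2e-11    46.5   0.0
o10                  -          P_a32                -            1e-30    99.9   0.0
o13                  -          P_polB               -            1e-11    48.7   0.0
o16                  -          P_mcp                -            1e-50    150.0  0.0
o17                  -          P_polB               -            1e-09    31.5   0.0
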