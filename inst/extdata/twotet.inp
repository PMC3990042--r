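** two tetrahedra sharing one face
*NODE
1, 0.0, 0.0, 0.0
2, 1.0, 0.0, 0.0
3, 0.0, 1.0, 0.0
4, 0.0, 0.0, 1.0
5, 1.0, 1.0, 1.0
*ELEMENT, TYPE=C3D4
1, 1, 2, 3, 4
2, 2, 3, 4, 5
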