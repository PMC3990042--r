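$MeshFormat
2.2 0 8
$EndMeshFormat
$Nodes
5
1 0.0 0.0 0.0
2 1.0 0.0 0.0
3 0.0 1.0 0.0
4 0.0 0.0 1.0
5 1.0 1.0 1.0
$EndNodes
$Elements
2
1 4 2 0 1 1 2 3 4
2 4 2 0 1 2 3 4 5
$EndElements
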