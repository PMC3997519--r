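#condition	compartment_class	feature
Aag2	nucleus_only	miR-1
Aag2	nucleus_only	miR-34-3p
Aag2	nucleus_only	miR-252-5p
Aag2	nucleus_only	miR-1889-3p
Aag2	nucleus_only	miR-1890
Aag2	cytoplasm_only	miR-125-5p
Aag2	cytoplasm_only	miR-137
Aag2	cytoplasm_only	miR-210
Aag2	cytoplasm_only	miR-282-5p
Aag2	cytoplasm_only	miR-285
Aag2	cytoplasm_only	miR-932-5p
Aag2	cytoplasm_only	miR-1174
Aag2	cytoplasm_only	miR-1175-3p
Aag2	cytoplasm_only	miR-1175-5p
Pop	nucleus_only	miR-11-5p
Pop	nucleus_only	miR-92a-5p
Pop	nucleus_only	miR-932-3p
Pop	nucleus_only	miR-965
Pop	nucleus_only	miR-988-5p
Pop	nucleus_only	miR-1175-5p
Pop	cytoplasm_only	miR-1
Pop	cytoplasm_only	miR-10
Pop	cytoplasm_only	miR-22
Pop	cytoplasm_only	miR-79-3p
Pop	cytoplasm_only	miR-137
Pop	cytoplasm_only	miR-219
Pop	cytoplasm_only	miR-263a-3p
Pop	cytoplasm_only	miR-285
Pop	cytoplasm_only	miR-286b
Pop	cytoplasm_only	miR-1174
Pop	cytoplasm_only	miR-1175
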