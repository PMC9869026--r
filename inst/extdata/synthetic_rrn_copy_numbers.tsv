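genus	copies
Defluviitoga	2
Methanothrix	2
Fermentimonas	4
Petrimonas	4
Syntrophomonas	5
Clostridium	8
Anaerolinea	2
Thermovirga	2
Desulfovibrio	4
Olsenella	3
Sebaldella	5
Phycisphaera	2
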