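# water-activity anchors for the Lake Hephaestus system
# conc: MgCl2, mol/L; aw: water activity
conc,aw,source
0.061,0.980,hephaestus
2.97,0.653,hephaestus
4.72,0.395,hephaestus
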