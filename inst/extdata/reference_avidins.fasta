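>avidin_chicken mature chicken avidin, UniProt P02701 residues 25-152
ARKCSLTGKWTNDLGSNMTIGAVNSRGEFTGTYITAVTATSNEIKESPLHGTQNTINKRT
QPTFGFTVNWKFSESTTVFTGQCFIDRNGKEVLKTMWLLRSSVNDIGDDWKATRVGINIF
TRLRTQKE
>streptavidin_core core streptavidin, UniProt P22629 residues 13-139 of the mature chain
AEAGITGTWYNQLGSTFIVTAGADGALTGTYESAVGNAESRYVLTGRYDSAPATDGSGTA
LGWTVAWKNNYRNAHSATTWSGQYVGGAEARINTQWLLTSGTTEANAWKSTLVGHDTFTK
VKPSAAS
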