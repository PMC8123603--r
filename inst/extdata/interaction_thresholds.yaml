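# Geometric distance cut-offs (Angstrom) for residue-interaction detection.
disulfide: 2.3
pi_pi: 7.0
cation_pi: 6.0
amino_pi: 6.0
his_pi: 7.0
sulfur_pi: 5.3
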