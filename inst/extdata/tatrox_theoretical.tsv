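# Theoretical masses of predicted mature peptides (average scale, >= 3000 Da)
# that match the packaged intact-mass fingerprint at 1.0 Da
peptide_id	theoretical_mass	family
TatNaTBet03	5196.79	beta-Na toxin
TatNaTBet08	6195.85	beta-Na toxin
TatKTxAlp10	3607.43	alpha-K toxin
TatKTxAlp12	4114.86	alpha-K toxin
TatCaTClc01	3788.48	calcin
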