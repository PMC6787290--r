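sample	ccs	reads_5p	reads_3p	reads_polyA	flnc	mean_flnc_length
KYSE140	557777	501590	516189	504004	445983	2539
KYSE510	602754	545561	558823	539496	477033	2442
SHEE	620818	555241	574085	559246	491354	2566
SHEEC	424278	376723	392202	386314	327459	2228
TE5	308010	284929	287900	283066	259482	3073
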