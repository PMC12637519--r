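;; SYNTHETIC sequences: composition-matched stand-ins for the ATG13 IDR
;; segment (residues 230-363) and ULK1 IDR segment (residues 277-831).
;; Generated from the package disorder-typical composition table with a
;; fixed seed; they match the stated segment lengths and a Pro/Ser-rich
;; IDR composition, not the database sequences.
>atg13_idr_230_363_synthetic
AGPKPDHAGLTASQPPEFSPPGKSSSAGTEKDDENLGPPTPVPPVALLFPYPRVPELQKI
QSSSIHELGHGSQLDKGSHPRASLRNSSLQGQAPEPGAPGRPTPVSSGSDMLSSKPSPPF
PITRGPSPASPYKL
>ulk1_idr_277_831_synthetic
SKTASPLPETDNEPPSRSSPQSIDGNMLPKSPPTTEMNTSRPMAAKHSQMNDRRYPGPNH
QSVQIPSEEDDSEESAKKSIYASPVVRLHQRAGQDGFDTLTERHPLTKRNDSQDIEPAAN
SQPVQEDLKAQDPMSEVENPSPEYHAEDKRSQSSDTPTQNGSDDGADPIGYAPETQGSPH
FRHRESNPAQPEQARSQPPLNPGKETPPFLSTPNTEPSGTSLRTKGRLDPELRPLEIMMS
ESNSAKTYLPVLGLERQRLRQRPGAQLLEFNPTSPAFPVMGSPVSMGEEPPRQATDFSRA
DSEGSRTMFSRASTQPVPVKMAENESKMILSTKTKPVKEASGPQRRYLPTNGQLRVEKAE
LQEPASAGSPDSHFDVTMSGWPYSVNPTAYLQYEPVKSLNSGHGKEPPFSSGASCPPEEG
PEAEVETYWSQGGCAVQMNEASNQGQEGETPELKKWSRPTAGQPHAHLKTSPSSLAQGVF
KPKHLKSRSVGGPGPHNGFLKRGANHSPLVGRELVKSGTTAGAQDAEEIQPSGGAVLIGA
KWSEGPLSVESSTSG
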