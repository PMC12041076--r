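Ache
Acta2
Adam10
Adamts2
Adarb2
Adora2a
Aldoc
Apoe
App
Aqp4
Arc
Arhgap36
Arntl
Atf4
Atxn1
Bace1
Bcl11b
Bdnf
Calb1
Calb2
Calca
Camk2a
Camk4
Cav1
Cblb
Cbln2
Cck
Ccr5
Cebpa
Chat
Chodl
Chrna2
Chrna6
Cnmd
Cpa6
Creb1
Crh
Crhr1
Crhr2
Crispld2
Cux1
Cux2
Dcn
Dcx
Deptor
Dicer1
Drd1
Egfr
Egr1
Eif2ak4
Eif2s1
Fev
Fezf2
Fos
Foxp2
Gabra1
Gabra2
Gad1
Gad2
Gfap
Gja1
Gls
Glul
Grin1
Grin2a
Grin2b
Hdac2
Homer1
Hpse
Igfbp4
Itgam
Kcnj8
Krt73
Lamp5
Laptm5
Lhx6
Lmo1
Lypd1
Map2
Mapk3
Mapt
Mbp
Mgll
Mmp9
Mup5
Ncam1
Ndnf
Nefh
Nes
Neurod1
Neurod6
Nf1
Npas4
Npy
Npy2r
Nrgn
Nrtn
Nt5c1a
Ntn1
Ntrk2
Nts
Oprk1
Oxt
P2rx3
Pcp4
Pdyn
Penk
Per1
Plat
Plch2
Plcxd2
Plp1
Ppp1r1b
Prox1
Psen1
Pthlh
Ptn
Ptprc
Pvalb
Rbbp4
Rbfox3
Reln
Rorb
Rprm
Rspo4
S1pr1
Satb2
Scn2a
Sema3e
Slc17a6
Slc17a7
Slc17a8
Slc6a1
Slc6a3
Slc6a4
Slc6a5
Sncg
Spp1
Sst
Syn1
Syt6
Sytl1
Tac1
Tac2
Tafa1
Tbr1
Th
Tpbg
Tph1
Trem2
Trh
Trhr
Trpv1
Tubb3
Unc5c
Vip
Vipr2
Wfs1
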