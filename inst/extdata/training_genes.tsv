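gene_id	label
Bmp4	positive
Cdyl	positive
Cdyl2	positive
Dmrt1	positive
Dppa4	positive
Dppa5a	positive
Esrrb	positive
Etv4	positive
Etv5	positive
Fgf4	positive
Foxd3	positive
Foxh1	positive
Gbx2	positive
Grhl2	positive
Jarid2	positive
Klf2	positive
Klf5	positive
Lefty2	positive
Lin28	positive
Mkrn1	positive
Mycn	positive
Nanog	positive
Nodal	positive
Nr0b1	positive
Nr5a2	positive
Phc1	positive
Phf17	positive
Pou4f2	positive
Pou5f1	positive
Rif1	positive
Sall1	positive
Sall4	positive
Sgk1	positive
Slc27a2	positive
Socs3	positive
Sox2	positive
Spp1	positive
Tcf15	positive
Tcfap2c	positive
Tcfcp2l1	positive
Tcl1	positive
Tle4	positive
Trp53	positive
Utf1	positive
Zfp296	positive
Zfp42	positive
Afp	negative
Arid3a	negative
Arid3b	negative
Ascl1	negative
Ascl2	negative
Bat1a	negative
Bmp2	negative
Bmp5	negative
Bmper	negative
Ccnd2	negative
Cdh2	negative
Cebpa	negative
Cited1	negative
Dach1	negative
Dlx1	negative
Dlx4	negative
Dlx6	negative
Ednra	negative
En1	negative
Eomes	negative
Ets2	negative
Eya2	negative
Fgf5	negative
Foxb1	negative
Gata1	negative
Gata3	negative
Gata4	negative
Gata5	negative
Gata6	negative
Gfap	negative
Gli3	negative
Gsc	negative
Hand1	negative
Hand2	negative
Insm1	negative
Isl1	negative
Lbx1	negative
Lhx2	negative
Lhx5	negative
Lmx1a	negative
Mbd2	negative
Meis1	negative
Mixl1	negative
Myf5	negative
Neurog1	negative
Nfia	negative
Npas3	negative
Nr2f1	negative
Nr2f2	negative
Nrp1	negative
Nrp2	negative
Olig3	negative
Otp	negative
Otx1	negative
Pax3	negative
Pdx1	negative
Peg3	negative
Phox2b	negative
Prl3d1	negative
Prox1	negative
Rybp	negative
Shh	negative
Sox1	negative
Sox18	negative
Sox3	negative
Sox5	negative
Sox9	negative
Stra13	negative
Syp	negative
Tcf4	negative
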