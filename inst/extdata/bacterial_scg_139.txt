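# Bacterial single-copy gene collection (139 genes, Campbell et al.);
# one identifier per line, in collection order.
Ribosomal_L1
Ribosomal_L2
Ribosomal_L3
Ribosomal_L4
Ribosomal_L5
Ribosomal_L6
Ribosomal_L9
Ribosomal_L10
Ribosomal_L11
Ribosomal_L13
Ribosomal_L14
Ribosomal_L16
Ribosomal_L17
Ribosomal_L18
Ribosomal_L19
Ribosomal_L20
Ribosomal_L21
Ribosomal_L22
Ribosomal_L23
Ribosomal_L24
Ribosomal_L25
Ribosomal_L27
Ribosomal_L28
Ribosomal_L29
Ribosomal_L30
Ribosomal_L32
Ribosomal_L33
Ribosomal_L34
Ribosomal_L35
Ribosomal_L36
Ribosomal_S2
Ribosomal_S3
Ribosomal_S4
Ribosomal_S5
Ribosomal_S6
Ribosomal_S7
Ribosomal_S8
Ribosomal_S9
Ribosomal_S10
Ribosomal_S11
Ribosomal_S12
Ribosomal_S13
Ribosomal_S15
Ribosomal_S16
Ribosomal_S17
Ribosomal_S18
Ribosomal_S19
Ribosomal_S20
Ala_tRNA_synt
Arg_tRNA_synt
Asn_tRNA_synt
Asp_tRNA_synt
Cys_tRNA_synt
Glu_tRNA_synt
Gly_tRNA_synt
His_tRNA_synt
Ile_tRNA_synt
Leu_tRNA_synt
Lys_tRNA_synt
Met_tRNA_synt
Phe_tRNA_synt
Pro_tRNA_synt
Ser_tRNA_synt
Thr_tRNA_synt
Trp_tRNA_synt
Tyr_tRNA_synt
Val_tRNA_synt
RNA_pol_alpha
RNA_pol_beta
RNA_pol_beta_prime
RNA_pol_omega
IF-1
IF-2
IF-3
EF-G
EF-Ts
EF-P
RF-1
RRF
LepA
SmpB
Tig
Pth
Map
Def
Fmt
DnaA
DnaB
DnaG
DnaN
DnaX
GyrA
GyrB
PolA
LigA
RecA
RecG
RecN
RecR
RuvA
RuvB
RuvC
TopA
UvrB
MutL
MutS
Ssb
PriA
RnhB
Nth
SecA
SecE
SecG
SecY
YidC
Ffh
FtsY
FtsA
FtsZ
Era
Der
Obg
YchF
EngB
RsgA
DnaJ
DnaK
GrpE
GroEL
ClpX
FtsH
NusA
NusB
NusG
GreA
Rho
RbfA
RimP
TruB
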