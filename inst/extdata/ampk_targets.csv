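site_label,protein_isoform,dephos_peptide,phos_peptide,charges_used,dominant_charge,reported_mz_dephos,reported_mz_phos,flyability_k
a1_S347,alpha1,DFYLATSPPDSFLDDHHLTRPHPER,DFYLATS[+80]PPDSFLDDHHLTRPHPER,4,4,741.6072,761.5988,0.58
a1_S477,alpha1,SGTATPQR,S[+80]GTATPQR,2,2,409.2118,449.1949,1.30
a1_T481,alpha1,SGTATPQR,SGTAT[+80]PQR,2,2,409.2118,449.1949,1.11
a1_S487,alpha1,SGSVSNYR,SGS[+80]VSNYR,1;2,2,435.2092,475.1924,1.10
a1_S499,alpha1,SDSDAEAQGK,SDS[+80]DAEAQGK,1;2,2,504.2174,544.2006,0.98
a2_S345,alpha2,IMNQASEFYLASSPPSGSFMDDSAMHIPPGLKPHPER,IMNQASEFYLASS[+80]PPSGSFMDDSAMHIPPGLKPHPER,5,5,809.1845,825.1777,0.83
a2_S377,alpha2,MPPLIADSPK,MPPLIADS[+80]PK,1;2,2,534.7915,574.7747,0.89
a2_S481,alpha2,SGSSTPQR,S[+80]GSSTPQR,1;2,2,410.2014,450.1846,1.35
a2_T485,alpha2,SGSSTPQR,SGSST[+80]PQR,1;2,2,410.2014,450.1846,1.18
a2_S501,alpha2,SSFDSTTAESHSLSGSLTGSLTGSTLSSVSPR,SS[+80]FDSTTAESHSLSGSLTGSLTGSTLSSVSPR,3;4,3,1048.5040,1075.1595,1.56
b1_S182,beta1,C[-1]SDVSELSSSPPGPYHQEPYVC[-1]KPEER,C[-1]SDVSELSSS[+80]PPGPYHQEPYVC[-1]KPEER,3;4,4,755.3366,775.3281,1.31
b2_S108,beta2,SHNDFVAILDLPEGEHQYK,S[+80]HNDFVAILDLPEGEHQYK,3;4,4,553.7722,573.7638,2.97
b2_S184,beta2,DLSSSPPGPYGQEMYAFR,DLSSS[+80]PPGPYGQEMYAFR,3,3,667.9719,694.6273,1.02
g2_S113,gamma2,TVFPFSYQESPPR,TVFPFSYQES[+80]PPR,2;3,2,777.8830,817.8662,5.11
g2_S143,gamma2,ESSPNSNPATSPGGIR,ESSPNSNPATS[+80]PGGIR,2;3,2,785.8764,825.8596,1.87
g2_S162,gamma2,TSGLSSSPSTPTQVTK,TSGLSSS[+80]PSTPTQVTK,2;3,2,789.4045,829.3877,2.79
g2_S196,gamma2,IYASSSPPDTGQR,IYASSS[+80]PPDTGQR,2;3;4,2,689.8335,729.8167,0.71
g3_S14,gamma3,TPSWSSLGGSEHQEMSFLEQENSSSWPSPAVTSSSER,TPS[+80]WSSLGGSEHQEMSFLEQENSSSWPSPAVTSSSER,3;4,4,1007.1987,1027.1903,0.99
g3_S65,gamma3,SVEEGEPPGQGEGPR,S[+80]VEEGEPPGQGEGPR,2,2,762.8499,802.8330,12.22
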