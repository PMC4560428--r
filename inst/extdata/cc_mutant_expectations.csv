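node,value,n_attractors,periods,basin_pct,grade,description
CYCD3;1,1,1,1,,PA,Fixed-point attractor of G2 phase
SCF,1,1,,,NR,Oscillates between G1 and S
RBR,1,1,1,,A,Fixed-point attractor characterizing G1 arrest
E2Fa,1,2,10;8,40.48;59.52,A,Wild-type-like cycle (40.48% of initial conditions) plus an endocycle-like attractor (59.52%)
E2Fb,1,1,,,A,Similar to wild type but with a shorter S phase
E2Fc,1,1,1,,PA,Fixed-point attractor with only E2Fc and CYCD3;1 present (cell-cycle arrest)
E2Fe,1,1,1,,PA,Cell-cycle arrest in M phase
MYB77,1,1,1,,-,Cell-cycle arrest in a mitotic state
MYB3R1/4,1,2,1;1,,-,Two fixed-point attractors of arrest at early G1; E2Fa state differs between them
CYCB1;1,1,1,11,,A,Wild-type cell cycle
CDKB1;1,1,1,11,,A,Wild-type cell cycle
CYCA2;3,1,1,11,,A,Wild-type cell cycle
KRP1,1,1,2,,PA,Period-2 attractor oscillating between G1 and the G1/S transition
APC/C,1,1,7,,A,Single period-7 cyclic attractor consistent with an endoreduplication cycle
CYCD3;1,0,1,2,,A,Period-2 attractor oscillating between G1 and the G1/S transition
SCF,0,1,,,A,Similar to a normal cell cycle; KRP1 stabilization would favor endoreduplication
RBR,0,2,11,81.98;18.02,A,Normal cell cycle (81.98% of configurations) plus an attractor oscillating among G2-S-G2 (18.02%)
E2Fa,0,1,1,,PA,Fixed point with E2Fe and CYCD3;1 present (arrest in a Gap phase)
E2Fb,0,1,1,,-,Fixed-point attractor representing the G1/S transition
E2Fc,0,1,1,,PA,Fixed-point attractor of M-phase arrest
E2Fe,0,1,7,,A,Attractor of endoreduplication (period 7)
MYB77,0,1,7,,-,Cell cycle of seven configurations
MYB3R1/4,0,2,3;7,,A,A three-configuration endocycle plus a seven-configuration cycle in which APC/C is always absent
CYCB1;1,0,1,8,,-,Endocycle attractor (period 8) in which APC/C is never present
CDKB1;1,0,1,7,,A,Single cyclic endoreduplication attractor with period 7
CYCA2;3,0,1,7,,PA,Endocycle attractor (period 7)
KRP1,0,1,11,100,A,A cell cycle without alterations (period 11; 100% of initial conditions)
APC/C,0,1,1,,PA,Fixed-point attractor of arrest previous to concluding mitosis
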