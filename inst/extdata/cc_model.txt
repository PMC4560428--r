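targets, factors
CYCD3;1, !SCF
SCF, (E2Fb & !RBR & !APC/C) | (!RBR & MYB3R1/4) | (E2Fb & MYB3R1/4)
RBR, (E2Fa & MYB3R1/4) | (!RBR & KRP1) | (MYB3R1/4 & KRP1)
E2Fa, (!E2Fc & !CYCA2;3 & !RBR) | (!E2Fc & !CDKB1;1 & !RBR)
E2Fb, E2Fa & !RBR
E2Fc, (E2Fa & !RBR & !CYCD3;1) | (!RBR & MYB3R1/4 & !CYCD3;1) | (!RBR & MYB3R1/4 & !SCF) | (E2Fa & MYB3R1/4 & !SCF) | (!SCF & !CYCD3;1 & KRP1) | (E2Fa & MYB3R1/4 & !CYCD3;1 & KRP1) | (MYB3R1/4 & !SCF & KRP1)
E2Fe, (!E2Fc & !RBR) | (MYB77 & !RBR) | (!E2Fc & MYB77) | (E2Fb & MYB77)
MYB77, E2Fb & !RBR
MYB3R1/4, (MYB77 & !KRP1 & !APC/C) | (MYB3R1/4 & CYCB1;1 & !KRP1 & !APC/C) | (MYB77 & CYCB1;1 & !APC/C) | (MYB77 & MYB3R1/4 & !KRP1) | (MYB77 & CYCB1;1 & !KRP1)
CYCB1;1, (E2Fb & !APC/C & !KRP1 & !RBR) | (MYB3R1/4 & !APC/C & !KRP1 & !RBR) | (E2Fb & !E2Fc & !KRP1 & !RBR) | (!E2Fc & MYB3R1/4 & !KRP1 & !RBR) | (E2Fb & MYB3R1/4 & !KRP1 & !RBR) | (E2Fb & !E2Fc & !APC/C & !RBR) | (!E2Fc & MYB3R1/4 & !APC/C & !RBR) | (E2Fb & MYB3R1/4 & !APC/C & !RBR) | (E2Fb & !E2Fc & MYB77 & !RBR) | (E2Fb & !E2Fc & MYB3R1/4 & !RBR) | (!E2Fc & MYB77 & MYB3R1/4 & !RBR) | (E2Fb & MYB77 & MYB3R1/4 & !RBR) | (!E2Fc & !KRP1 & CDKB1;1 & !RBR) | (MYB77 & !KRP1 & CDKB1;1 & !RBR) | (!APC/C & CDKB1;1 & !RBR) | (E2Fb & !E2Fc & CDKB1;1 & !RBR) | (E2Fb & MYB77 & CDKB1;1 & !RBR) | (E2Fb & MYB3R1/4 & CDKB1;1 & !RBR) | (E2Fb & !E2Fc & !APC/C & !KRP1) | (E2Fb & MYB77 & !APC/C & !KRP1) | (E2Fb & !E2Fc & MYB77 & !APC/C) | (E2Fb & !E2Fc & MYB3R1/4 & !APC/C) | (!E2Fc & MYB77 & MYB3R1/4 & !APC/C) | (!E2Fc & !APC/C & !KRP1 & CDKB1;1) | (E2Fb & !APC/C & !KRP1 & CDKB1;1) | (MYB77 & !APC/C & !KRP1 & CDKB1;1) | (E2Fb & !E2Fc & !KRP1 & CDKB1;1) | (!E2Fc & MYB77 & !KRP1 & CDKB1;1) | (MYB77 & MYB3R1/4 & !KRP1 & CDKB1;1) | (E2Fb & !E2Fc & !APC/C & CDKB1;1) | (!E2Fc & MYB77 & !APC/C & CDKB1;1) | (!E2Fc & MYB3R1/4 & !APC/C & CDKB1;1) | (E2Fb & MYB77 & MYB3R1/4 & !APC/C & CDKB1;1) | (E2Fb & !E2Fc & MYB3R1/4 & CDKB1;1)
CDKB1;1, (MYB3R1/4 & !E2Fc) | MYB77 | (E2Fb & MYB3R1/4)
CYCA2;3, (MYB77 & !APC/C) | MYB3R1/4 | (MYB77 & CYCA2;3)
KRP1, (MYB77 & !CYCA2;3 & !SCF) | (MYB3R1/4 & !CDKB1;1 & !SCF) | (MYB3R1/4 & !CYCA2;3)
APC/C, (E2Fa & !RBR & !E2Fe) | (!RBR & MYB77 & !E2Fe) | (E2Fa & MYB77 & !E2Fe) | (!RBR & MYB3R1/4 & !E2Fe) | (MYB77 & MYB3R1/4 & !E2Fe) | (E2Fa & !RBR & MYB3R1/4) | (!RBR & MYB77 & MYB3R1/4)
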