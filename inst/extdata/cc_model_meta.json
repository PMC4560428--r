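{
  "nodes": ["CYCD3;1", "SCF", "RBR", "E2Fa", "E2Fb", "E2Fc", "E2Fe", "MYB77", "MYB3R1/4", "CYCB1;1", "CDKB1;1", "CYCA2;3", "KRP1", "APC/C"],
  "phase_scheme": {
    "labels": ["G1", "G1", "G1/S", "S", "S/G2", "S/G2", "G2", "G2/M", "M", "M", "M-exit"],
    "anchor": {
      "complex_off": ["CYCD3;1", "KRP1"],
      "on": ["APC/C", "RBR"],
      "off": ["CYCB1;1", "CYCA2;3"]
    }
  },
  "provenance": {
    "CYCD3;1": "Cyclin D3;1 (CDKA;1 partner); degraded via SCF-mediated ubiquitination; complex activity blocked by KRP1 binding.",
    "SCF": "SCF E3 ubiquitin ligase; Skp2-type subunit transcription driven by E2F and MYB3R factors; antagonized by APC/C.",
    "RBR": "RETINOBLASTOMA-RELATED; ON = hypo-phosphorylated (E2F-inhibitory) form; inactivated by CDKA;1-CYCD3;1 phosphorylation; transcription supported by E2Fa and MYB3R1/4.",
    "E2Fa": "Activator E2F; repressed by E2Fc, destabilized by CDKB1;1-CYCA2;3 phosphorylation; its transcriptional output requires RBR-free state (gated at targets).",
    "E2Fb": "Activator E2F; transcribed by RBR-free E2Fa.",
    "E2Fc": "Repressor E2F; induced by E2Fa/MYB3R1/4; degraded when phosphorylated by CDKA;1-CYCD3;1 and recognized by SCF.",
    "E2Fe": "Atypical E2F (DEL); E2F-site target activated by E2Fb/MYB77 and repressed by E2Fc.",
    "MYB77": "MYB transcription factor linking the E2F wave to the mitotic MYB3R wave; induced by E2Fb.",
    "MYB3R1/4": "MSA-binding MYB3R activators of G2/M genes; induced by MYB77; autoregulatory, stimulated by CDKA;1-CYCB1;1 (blocked by KRP1), shut down by APC/C-era degradation of CYCB1;1.",
    "CYCB1;1": "Mitotic cyclin; transcription by E2Fb/MYB77/MYB3R1/4, repressed by E2Fc, degraded by APC/C.",
    "CDKB1;1": "Plant-specific B-type CDK; transcription by E2Fb/MYB77/MYB3R1/4, repressed by E2Fc; partners CYCA2;3.",
    "CYCA2;3": "Mitotic A-type cyclin; transcription by MYB77/MYB3R1/4; degraded by APC/C.",
    "KRP1": "Kip-related CDK inhibitor; induced by MYB77/MYB3R1/4; degraded after CDKB1;1-CYCA2;3 phosphorylation and SCF recognition.",
    "APC/C": "Anaphase-promoting complex/cyclosome (CCS52A2 activator); induced by RBR-free E2Fa and MYB factors; CCS52A2 transcription repressed by E2Fe."
  }
}
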