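## Access to the compiled per-context cycle-probability matrix (rows:
## untreated, treated, clinical_af; cols: 4 event types, death, progression).
compile_for_test <- function(cfg) noacaf:::compile_model(cfg)$prob_mat
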