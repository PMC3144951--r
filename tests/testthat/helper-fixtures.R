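# Shared fixture builders; everything is generated in code.

# Triplicate well table with exact Ct means (no noise).
make_wells <- function(samples, ct_target, ct_control, replicates = 3L) {
  do.call(rbind, lapply(seq_along(samples), function(i) {
    data.frame(
      sample_id = samples[i],
      assay = rep(c("target", "control"), each = replicates),
      replicate = rep(seq_len(replicates), 2L),
      ct = rep(c(ct_target[i], ct_control[i]), each = replicates),
      stringsAsFactors = FALSE)
  }))
}

# The published 27-nt IRE element (DNA spelling, as printed).
IRE_27MER <- "ctttgctgcgtcagtgaacgtacgagc"
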