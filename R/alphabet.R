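# RNA alphabet and the admissible base-pairing rule, shared across modules.

RNA_BASES <- c("A", "C", "G", "U")

# the six allowed ordered pairs, fixed order
.ALLOWED_PAIRS <- matrix(c("A", "U",
                           "U", "A",
                           "G", "C",
                           "C", "G",
                           "G", "U",
                           "U", "G"), ncol = 2L, byrow = TRUE,
                         dimnames = list(NULL, c("left", "right")))

# 4x4 compatibility (TRUE where the ordered pair may bind)
.PAIR_OK <- local({
  m <- matrix(FALSE, 4L, 4L, dimnames = list(RNA_BASES, RNA_BASES))
  for (q in seq_len(nrow(.ALLOWED_PAIRS)))
    m[.ALLOWED_PAIRS[q, 1L], .ALLOWED_PAIRS[q, 2L]] <- TRUE
  m
})
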