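# Small fixtures shared across test files.

# 2 samples per group; `rows` is a list of length-8 numeric vectors in
# group order CTL, CTL, BPA, BPA, RAD, RAD, BPA_RAD, BPA_RAD.
tiny_matrix <- function(rows, gene_ids = sprintf("g%d", seq_along(rows)),
                        is_coding = NULL) {
  values <- do.call(rbind, rows)
  groups <- rep(group_levels(), each = 2)
  sheet <- data.frame(
    sample = paste(groups, rep(1:2, 4), sep = "_"),
    bpa = as.integer(groups %in% c("BPA", "BPA_RAD")),
    rad = as.integer(groups %in% c("RAD", "BPA_RAD")))
  expr_matrix(values, gene_ids, sheet, is_coding)
}

# scalar reference classifier used as the independent oracle: literal
# case-by-case enumeration of sign patterns and ratio bins
oracle_classify_one <- function(b, r, cmb, lo = 0.8, hi = 1.2, eps = 1e-8) {
  s <- b + r
  if (abs(s) < eps) return("unexpected")
  if (cmb != 0) {
    same_sign <- (cmb > 0 && s > 0) || (cmb < 0 && s < 0)
    if (!same_sign) return("unexpected")
  }
  rat <- abs(cmb) / abs(s)
  if (rat > hi) return("potentiation")
  if (rat < lo) return("antagonism")
  "additive"
}
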