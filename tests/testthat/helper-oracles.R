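# Brute-force greedy reference implementations shared by the unit and
# acceptance suites.

# independent greedy reference: operates on plain data.frames, sets, and a
# dense r2 matrix; intentionally different code shape from clump()
oracle_clump <- function(df, r2mat, clump_p, clump_r2, window) {
  todo <- df[df$p < clump_p, ]
  todo <- todo[order(todo$p, todo$chrom, todo$pos_bp), ]
  out <- character()
  while (nrow(todo) > 0) {
    head <- todo[1, ]
    out <- c(out, head$variant_id)
    drop <- rep(FALSE, nrow(todo))
    for (i in seq_len(nrow(todo))[-1]) {
      if (todo$chrom[i] == head$chrom &&
          abs(todo$pos_bp[i] - head$pos_bp) <= window &&
          r2mat[head$variant_id, todo$variant_id[i]] > clump_r2) {
        drop[i] <- TRUE
      }
    }
    todo <- todo[-c(1, which(drop)), , drop = FALSE]
  }
  out
}

oracle_merge <- function(df, merge_cm) {
  df <- df[order(df$min_p, df$chrom, df$pos_bp), ]
  kept <- df[0, ]
  for (i in seq_len(nrow(df))) {
    close <- kept$chrom == df$chrom[i] & abs(kept$cm - df$cm[i]) < merge_cm
    if (!any(close)) kept <- rbind(kept, df[i, ])
  }
  kept$variant_id
}
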