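# Independent brute-force oracles and small fixtures. These deliberately
# re-derive quantities with naive code (explicit loops, hand-written
# interpolation) so they stay independent of the implementation they check.

# percentile by explicit order statistics, h = 1 + (n-1)k/100
brute_percentile <- function(x, k) {
  s <- sort(x)
  n <- length(s)
  h <- 1 + (n - 1) * k / 100
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# d_IJ by full pairwise distance matrix, explicit min, explicit percentile
brute_dIJ <- function(cur_mat, ref_mat, k) {
  dnJ <- numeric(nrow(cur_mat))
  for (i in seq_len(nrow(cur_mat))) {
    best <- Inf
    for (j in seq_len(nrow(ref_mat))) {
      d <- sqrt(sum((cur_mat[i, ] - ref_mat[j, ])^2))
      if (d < best) best <- d
    }
    dnJ[i] <- best
  }
  brute_percentile(dnJ, k)
}

# Welch statistic, Welch-Satterthwaite e.d.o.f. and lower-tail p by direct
# formula evaluation
brute_welch <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- sum((a - mean(a))^2) / (na - 1)
  vb <- sum((b - mean(b))^2) / (nb - 1)
  se2 <- va / na + vb / nb
  t <- (mean(a) - mean(b)) / sqrt(se2)
  edof <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = t, edof = edof, p = pt(t, edof))
}

# two-species embedded fixture with hand-placed points
toy_lineage_row <- function(species, genus = "G", family = "F",
                            class = "C", phylum = "P", kingdom = "K") {
  data.frame(species = species, genus = genus, family = family,
             class = class, phylum = phylum, kingdom = kingdom,
             stringsAsFactors = FALSE)
}

make_toy_fixture <- function() {
  # species A: molecules at (0,0), (1,0); species B: (1,0), (0,2), (10,10)
  rec <- rbind(
    cbind(data.frame(molecule_id = c("a1", "shared"), smiles = c("CC", "CCO"),
                     stringsAsFactors = FALSE),
          toy_lineage_row("A", genus = "G1")[rep(1, 2), ]),
    cbind(data.frame(molecule_id = c("shared", "b2", "b3"),
                     smiles = c("CCO", "CCN", "CCCC"), stringsAsFactors = FALSE),
          toy_lineage_row("B", genus = "G1")[rep(1, 3), ]))
  ds <- np_dataset(rec)
  mat <- rbind(a1 = c(0, 0), shared = c(1, 0), b2 = c(0, 2), b3 = c(10, 10))
  list(ds = ds, table = embedding_table(mat, "toy"))
}

# write a small occurrence CSV; returns the path
write_toy_csv <- function(rows, path = tempfile(fileext = ".csv")) {
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  path
}

toy_occurrence_rows <- function() {
  data.frame(smiles = c("CCO", "CCN", "CCC", "CCCC", "CCCCC"),
             species = c("s1", "s1", "s2", "s2", "s3"),
             genus = c("g1", "g1", "g1", "g1", "g2"),
             family = "f1", class = "c1", phylum = "p1", kingdom = "k1",
             stringsAsFactors = FALSE)
}
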