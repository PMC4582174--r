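# Shared fixtures built in code. The adapter is a common small-RNA 3'
# adapter sequence; the tiny reference carries a miR-10-like family pair
# plus a planted duplicate-sequence pair to exercise the merge rule.

TEST_ADAPTER <- "TGGAATTCTCGGGTGCCAAGG"

test_reference <- function() {
  mature_reference(
    names = c("hsa-miR-10a-5p", "hsa-miR-10b-5p", "hsa-miR-92a-3p",
              "hsa-miR-124-3p", "hsa-miR-9-5p", "hsa-miR-9-alt"),
    families = c("miR-10", "miR-10", "miR-92", "miR-124", "miR-9", "miR-9"),
    sequences = c("UACCCUGUAGAUCCGAAUUUGUG",
                  "UACCCUGUAGAACCGAAUUUGUG",
                  "UAUUGCACUUGUCCCGGCCUGU",
                  "UAAGGCACGCGGUGAAUGCC",
                  "UCUUUGGUUAUCUAGCUGUAUGA",
                  "UCUUUGGUUAUCUAGCUGUAUGA"))  # duplicate of miR-9-5p
}

# Random DNA sequences of given lengths, avoiding accidental adapter hits
# when alphabet excludes the adapter's distinguishing letters is not
# attempted; callers that need adapter-free reads pass alphabet.
random_seqs <- function(n, lengths, alphabet = c("A", "C", "G", "T")) {
  vapply(lengths, function(L)
    paste(sample(alphabet, L, replace = TRUE), collapse = ""), "")
}

# Brute-force adapter trimming oracle: scan every start position for the
# full adapter, then every suffix/prefix overlap down to min_overlap.
trim_oracle <- function(read, adapter, min_overlap) {
  n <- nchar(read); a <- nchar(adapter)
  for (i in seq_len(max(n - a + 1, 0)))
    if (substr(read, i, i + a - 1) == adapter)
      return(substr(read, 1, i - 1))
  for (k in seq(min(a - 1, n), 1)) {
    if (k < min_overlap) break
    if (substr(read, n - k + 1, n) == substr(adapter, 1, k))
      return(substr(read, 1, n - k))
  }
  read
}

# Brute-force two-sample KS statistic: maximal ECDF gap evaluated over the
# pooled data points.
ks_d_oracle <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(abs(vapply(pts, function(t) mean(x <= t) - mean(y <= t), 0)))
}

# A small expression experiment wrapper with common defaults used across
# target-inference tests (kept small for speed).
small_mrna_sim <- function(n_genes = 2000, seed = 1, ...) {
  simulate_mrna_overexpression(n_genes = n_genes, n_targets = 40,
                               n_decoys = 40, seed = seed, ...)
}
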