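# Small in-code fixtures used across tests.

# Build an annotated alignment from named sequence strings.
toy_alignment <- function(seqs, loci = NULL) {
  mat <- do.call(rbind, strsplit(unlist(seqs), ""))
  rownames(mat) <- names(seqs)
  if (is.null(loci)) loci <- locus_index("cne1.1.1", ncol(mat))
  annotated_alignment(mat, loci)
}

# Four specimens, six columns; column 2 is the only diagnostic one for
# {s1, s2} (C vs T), used throughout the diagnostics tests.
TOY1 <- toy_alignment(c(s1 = "ACGTAC", s2 = "ACGTAC",
                        s3 = "ATGTAC", s4 = "ATGTAC"))

# Random alignment with clade structure absent: i.i.d. bases, optional
# missing/ambiguity sprinkle. Returns the alignment plus a random member set.
random_alignment <- function(n_spec, n_cols, p_missing = 0.1,
                             p_ambig = 0.02, alphabet = c("A", "C", "G", "T")) {
  symbols <- sample(alphabet, n_spec * n_cols, replace = TRUE)
  extra <- runif(n_spec * n_cols)
  symbols[extra < p_missing] <- sample(c("N", "-"), sum(extra < p_missing),
                                       replace = TRUE)
  amb <- extra >= p_missing & extra < p_missing + p_ambig
  symbols[amb] <- sample(c("R", "Y", "W"), sum(amb), replace = TRUE)
  mat <- matrix(symbols, n_spec, n_cols,
                dimnames = list(sprintf("s%02d", seq_len(n_spec)), NULL))
  annotated_alignment(mat, locus_index("cne9.9.9", n_cols))
}

# sample() treats a length-1 numeric as 1:x; pick1 never does.
pick1 <- function(x) x[sample.int(length(x), 1L)]

# Random valid diagnostic characters for round-trip testing.
random_characters <- function(n) {
  kinds <- sample(c("direct", "state_only", "retained_not"), n, replace = TRUE)
  loci <- sample(c("COI", sprintf("cne%d.%d.%d", sample(1:40000, n, TRUE),
                                  sample(1:30, n, TRUE),
                                  sample(1:40, n, TRUE))), n, replace = TRUE)
  pos <- sample(1:9999, n, replace = TRUE)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    if (kinds[i] == "direct") {
      anc <- sample(c("A", "C", "G", "T"), 1)
      der <- sample(setdiff(c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M"),
                            anc), 1)
      out[[i]] <- diag_characters(loci[i], pos[i], ancestral = anc,
                                  derived = der, kind = "direct")
    } else if (kinds[i] == "state_only") {
      out[[i]] <- diag_characters(loci[i], pos[i], ancestral = NA,
                                  derived = sample(c("A", "C", "G", "T"), 1),
                                  kind = "state_only")
    } else {
      st <- sample(c("A", "C", "G", "T"), 1)
      out[[i]] <- diag_characters(loci[i], pos[i], ancestral = st,
                                  derived = st, kind = "retained_not",
                                  excluded_state = sample(setdiff(
                                    c("A", "C", "G", "T"), st), 1),
                                  scope = "sister_negated")
    }
  }
  do.call(taxodiag:::rbind_characters, out)
}
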