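options(ecgc.verbose = FALSE)

# small random genotype object (doses in {0,1,2}) with a marker map
h_geno <- function(n = 50, m = 200, seed = 1, n_chrom = 2) {
  set.seed(seed)
  p <- runif(m, 0.1, 0.9)
  doses <- matrix(rbinom(n * m, 2L, rep(p, each = n)), n,
                  dimnames = list(sprintf("V%03d", seq_len(n)),
                                  sprintf("S%04d", seq_len(m))))
  chrom <- sort(sprintf("chr%d", rep(seq_len(n_chrom), length.out = m)))
  bp <- unlist(lapply(split(seq_len(m), chrom), function(ix)
    sort(sample.int(1e7, length(ix)))), use.names = FALSE)
  structure(list(doses = doses,
                 map = data.frame(snp = colnames(doses), chrom = chrom,
                                  bp = bp, stringsAsFactors = FALSE)),
            class = "ecgc_geno")
}

# geno object from an explicit dose matrix
h_geno_from <- function(doses) {
  if (is.null(colnames(doses)))
    colnames(doses) <- sprintf("S%04d", seq_len(ncol(doses)))
  if (is.null(rownames(doses)))
    rownames(doses) <- sprintf("V%03d", seq_len(nrow(doses)))
  structure(list(doses = doses,
                 map = data.frame(snp = colnames(doses), chrom = "chr1",
                                  bp = seq_len(ncol(doses)),
                                  stringsAsFactors = FALSE)),
            class = "ecgc_geno")
}

# lower Cholesky factor for sampling correlated effects
h_chol <- function(G) t(chol(G + diag(1e-6, nrow(G))))
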