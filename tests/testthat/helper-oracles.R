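# Independent oracles: hand-summed tails, direct likelihood maximisation and
# brute-force enumerations that the implementation is checked against.

# Exact upper-tail binomial probability P(X >= m) by summing point masses.
binom_tail_oracle <- function(m, n, e) {
  if (m <= 0) return(1)
  sum(stats::dbinom(m:n, n, e))
}

# Exact upper-tail hypergeometric via binomial coefficients.
hyper_tail_oracle <- function(k, K, N, s) {
  if (k <= 0) return(1)
  i <- k:min(K, s)
  sum(choose(K, i) * choose(N - K, s - i)) / choose(N, s)
}

# Direct maximisation of the binomial-GLM log-likelihood (logit link),
# independent of stats::glm's IRLS.
log1pexp <- function(x) ifelse(x > 0, x + log1p(exp(-x)), log1p(exp(x)))

max_binom_loglik <- function(X, m, n) {
  nll <- function(b) {
    eta <- drop(X %*% b)
    -sum(m * eta - n * log1pexp(eta))
  }
  gr <- function(b) {
    mu <- stats::plogis(drop(X %*% b))
    -drop(t(X) %*% (m - n * mu))
  }
  o <- stats::optim(rep(0, ncol(X)), nll, gr, method = "BFGS",
                    control = list(maxit = 2000, reltol = 1e-15))
  -o$value
}

# LRT statistic for the group effect from two direct likelihood
# maximisations on the same data the package model sees.
glm_lrt_oracle <- function(d, comparison, covariate = NULL) {
  grp <- factor(d$group, levels = comparison)
  X_full <- if (is.null(covariate)) {
    stats::model.matrix(~grp)
  } else {
    stats::model.matrix(~ grp + cov, data.frame(grp = grp,
                                                cov = factor(d[[covariate]])))
  }
  X_null <- X_full[, colnames(X_full) != paste0("grp", comparison[2]),
                   drop = FALSE]
  2 * (max_binom_loglik(X_full, d$m, d$n) -
         max_binom_loglik(X_null, d$m, d$n))
}

# Brute-force synonymous-substitution counts for one codon position from the
# genetic code directly.
brute_syn_count <- function(codon, pos) {
  code <- Biostrings::GENETIC_CODE
  aa <- code[[codon]]
  alt <- setdiff(c("A", "C", "G", "T"), substr(codon, pos, pos))
  muts <- vapply(alt, function(b) {
    m <- codon
    substr(m, pos, pos) <- b
    m
  }, character(1))
  sum(code[muts] == aa & code[muts] != "*")
}

# Beta log-likelihood, for checking the packaged fit against an independent
# Nelder-Mead maximisation.
beta_negll <- function(par, X, y) {
  p <- ncol(X)
  mu <- stats::plogis(drop(X %*% par[seq_len(p)]))
  phi <- exp(par[p + 1])
  -sum(stats::dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE))
}

# Inject k synonymous and j non-synonymous single-base substitutions into a
# clean CDS, one per distinct codon, choosing substitutions by translating
# candidate codons against the genetic code (constructive oracle for pN/pS).
inject_snvs <- function(cds, k_syn, j_nonsyn) {
  code <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  codons <- codons_split(cds)
  n_cod <- length(codons)
  usable <- 2:(n_cod - 1)  # keep start and stop codons untouched
  picked <- sample(usable)
  mutant <- cds
  done_s <- done_n <- 0L
  for (ci in picked) {
    if (done_s >= k_syn && done_n >= j_nonsyn) break
    codon <- codons[ci]
    aa <- code[[codon]]
    cand <- list()
    for (p in 1:3) {
      for (b in setdiff(bases, substr(codon, p, p))) {
        m <- codon
        substr(m, p, p) <- b
        if (code[[m]] == "*") next
        cand[[length(cand) + 1L]] <- list(
          pos = p, base = b, syn = code[[m]] == aa
        )
      }
    }
    syn_c <- Filter(function(x) x$syn, cand)
    non_c <- Filter(function(x) !x$syn, cand)
    pick <- NULL
    type <- NULL
    if (done_s < k_syn && length(syn_c) > 0) {
      pick <- syn_c[[sample.int(length(syn_c), 1)]]
      type <- "syn"
    } else if (done_n < j_nonsyn && length(non_c) > 0) {
      pick <- non_c[[sample.int(length(non_c), 1)]]
      type <- "nonsyn"
    }
    if (is.null(pick)) next
    site <- (ci - 1L) * 3L + pick$pos
    substr(mutant, site, site) <- pick$base
    if (type == "syn") done_s <- done_s + 1L else done_n <- done_n + 1L
  }
  if (done_s < k_syn || done_n < j_nonsyn) return(NULL)
  mutant
}

codons_split <- function(seq) {
  n <- nchar(seq)
  substring(seq, seq(1, n, 3), seq(3, n, 3))
}
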