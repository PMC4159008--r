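# Nei-Gojobori (1986) counting estimator of dN and dS: synonymous site
# fractions averaged over the two sequences, pathway-averaged difference
# counting between codons, and the Jukes-Cantor multiple-hit correction.
# Serves as a fast model-free cross-check of the ML estimates.

# synonymous site count per sense codon (changes to stop codons are excluded
# from the mutational opportunities at each position)
.ng86_sites <- function() {
  if (exists("ng86_s", envir = .codon_env)) return(get("ng86_s", envir = .codon_env))
  cods <- sense_codons(); aa <- codon_amino_acids()
  cm <- .code("codon_nt")
  s <- numeric(61)
  for (i in 1:61) {
    tot <- 0
    for (p in 1:3) {
      alt <- .nt[.nt != cm[i, p]]
      targets <- vapply(alt, function(x) {
        cd <- cm[i, ]; cd[p] <- x; paste0(cd, collapse = "")
      }, character(1))
      sense <- targets[targets %in% cods]
      if (length(sense) == 0) next
      syn <- sum(aa[match(sense, cods)] == aa[i])
      tot <- tot + syn / length(sense)
    }
    s[i] <- tot
  }
  assign("ng86_s", s, envir = .codon_env)
  s
}

# pathway-averaged (syn, nonsyn) difference counts between two sense codons;
# paths through stop codons are discarded, falling back to all paths if every
# ordering is blocked
.ng86_diffs <- function(i, j) {
  cods <- sense_codons(); aa <- codon_amino_acids()
  cm <- .code("codon_nt")
  pos <- which(cm[i, ] != cm[j, ])
  if (length(pos) == 0) return(c(0, 0))
  count_path <- function(order) {
    cur <- cm[i, ]; sd <- 0; nd <- 0
    for (p in order) {
      nxt <- cur; nxt[p] <- cm[j, p]
      from <- paste0(cur, collapse = ""); to <- paste0(nxt, collapse = "")
      ito <- match(to, cods)
      if (is.na(ito)) return(NULL)             # path passes through a stop
      ifrom <- match(from, cods)
      if (aa[ifrom] == aa[ito]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd, nd)
  }
  orders <- if (length(pos) == 1) list(pos) else
    lapply(seq_len(nrow(perms <- .permutations(pos))), function(k) perms[k, ])
  counted <- Filter(Negate(is.null), lapply(orders, count_path))
  if (length(counted) == 0) {
    # all orderings blocked by stops: count each differing position directly
    sd <- 0
    for (p in pos) {
      nxt <- cm[i, ]; nxt[p] <- cm[j, p]
      ito <- match(paste0(nxt, collapse = ""), cods)
      if (!is.na(ito) && aa[i] == aa[ito]) sd <- sd + 1
    }
    return(c(sd, length(pos) - sd))
  }
  colMeans(do.call(rbind, counted))
}

.permutations <- function(x) {
  if (length(x) == 1) return(matrix(x, 1))
  out <- NULL
  for (k in seq_along(x))
    out <- rbind(out, cbind(x[k], .permutations(x[-k])))
  out
}

#' Pairwise dN/dS by NG86 counting
#'
#' Nei-Gojobori (1986) estimates: synonymous/nonsynonymous site counts
#' averaged over the two sequences, pathway-averaged substitution counting at
#' differing codons, and Jukes-Cantor correction of the proportions. A
#' proportion >= 3/4 cannot be corrected and is returned as `NA` with
#' `saturated = TRUE`.
#'
#' @inheritParams pairwise_dnds_ml
#' @return Object of class `pairwise_dnds` with `method = "NG86"`, fields
#'   `dn`, `ds`, `omega` (NA when ds is 0 or saturated), site counts `S` and
#'   `N`, and a `saturated` flag.
#' @export
ng86_dnds <- function(a, b = NULL, pair = c("a", "b")) {
  if (inherits(a, "codon_alignment")) {
    stopifnot(length(a$labels) == 2)
    pair <- a$labels
    b <- a$sequences[[2]]; a <- a$sequences[[1]]
  }
  pp <- pair_patterns(a, b, pair)
  svec <- .ng86_sites()
  expand <- rep(seq_along(pp$w), pp$w)
  ia <- pp$sa[expand]; ib <- pp$sb[expand]
  S <- (sum(svec[ia]) + sum(svec[ib])) / 2
  N <- 3 * length(ia) - S
  diffs <- mapply(function(x, y) .ng86_diffs(x, y), pp$sa, pp$sb)
  Sd <- sum(diffs[1, ] * pp$w)
  Nd <- sum(diffs[2, ] * pp$w)
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  ps <- Sd / S; pn <- Nd / N
  ds <- jc(ps); dn <- jc(pn)
  saturated <- is.na(ds) || is.na(dn)
  omega <- if (!saturated && ds > 0) dn / ds else NA_real_
  structure(list(pair = pair, dn = dn, ds = ds, omega = omega,
                 S = S, N = N, Sd = Sd, Nd = Nd,
                 n_codons = pp$n_used, method = "NG86",
                 saturated = saturated),
            class = "pairwise_dnds")
}
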