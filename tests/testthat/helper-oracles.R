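# Independent oracles used to cross-check the package implementations.
# These deliberately re-derive each quantity by direct enumeration, never by
# calling the code paths they check.

# Brute-force k-NN imputation: loops over donors, recomputes standardization,
# missing-aware distances and inverse-distance weights from first principles.
oracle_knn_impute <- function(table, k) {
  vals <- table$values
  mask <- table$missing_mask
  n <- nrow(vals); p <- ncol(vals)
  mu <- numeric(p); sg <- numeric(p)
  for (j in seq_len(p)) {
    obs <- vals[!mask[, j], j]
    mu[j] <- mean(obs)
    sg[j] <- stats::sd(obs)
    if (!is.finite(sg[j]) || sg[j] == 0) sg[j] <- 1
  }
  out <- vals
  for (i in seq_len(n)) {
    for (v in which(mask[i, ])) {
      cand <- data.frame(j = integer(0), d = numeric(0))
      for (j in setdiff(seq_len(n), i)) {
        if (mask[j, v]) next
        shared <- which(!mask[i, ] & !mask[j, ])
        if (length(shared) == 0) next
        d2 <- 0
        for (s in shared) {
          zi <- (vals[i, s] - mu[s]) / sg[s]
          zj <- (vals[j, s] - mu[s]) / sg[s]
          d2 <- d2 + (zi - zj)^2
        }
        cand <- rbind(cand, data.frame(j = j, d = sqrt(d2 / length(shared))))
      }
      stopifnot(nrow(cand) > 0)
      cand <- cand[order(cand$d, cand$j), ]
      top <- cand[seq_len(min(k, nrow(cand))), ]
      if (any(top$d == 0)) {
        zd <- top[top$d == 0, ]
        out[i, v] <- mean(vals[zd$j, v])
      } else {
        w <- 1 / top$d
        out[i, v] <- sum(w * vals[top$j, v]) / sum(w)
      }
    }
  }
  out
}

# Exhaustive supervised-discretization oracle: enumerates every subset of
# the candidate boundaries and scores each partition directly.
oracle_bayes_disc_score <- function(values, class_labels, lambda) {
  keep <- !is.na(values)
  x <- values[keep]; y <- class_labels[keep] == "positive"
  ord <- order(x); x <- x[ord]; y <- y[ord]
  ux <- unique(x)
  npos <- sapply(ux, function(v) sum(y[x == v]))
  nneg <- sapply(ux, function(v) sum(!y[x == v]))
  m <- length(ux)
  seg_ll <- function(from, to) {
    np <- sum(npos[(from + 1):to]); nn <- sum(nneg[(from + 1):to])
    lgamma(np + 1) + lgamma(nn + 1) - lgamma(np + nn + 2)
  }
  prop <- npos / (npos + nneg)
  cand <- if (m > 1) which(abs(diff(prop)) > 1e-12) else integer(0)
  best <- -Inf; best_cuts <- integer(0)
  subsets <- if (length(cand) == 0) list(integer(0)) else {
    idx <- unlist(lapply(0:length(cand), function(sz)
      utils::combn(cand, sz, simplify = FALSE)), recursive = FALSE)
    idx
  }
  for (cuts in subsets) {
    bnds <- c(0, sort(cuts), m)
    sc <- -length(cuts) * log(lambda)
    for (s in seq_len(length(bnds) - 1))
      sc <- sc + seg_ll(bnds[s], bnds[s + 1])
    if (sc > best + 1e-12 ||
        (abs(sc - best) <= 1e-12 && length(cuts) < length(best_cuts))) {
      best <- sc
      best_cuts <- sort(cuts)
    }
  }
  list(score = best, cut_points = (ux[best_cuts] + ux[best_cuts + 1]) / 2)
}

# Score of a returned cut set, computed independently (to compare the DP's
# chosen partition against the exhaustive maximum).
oracle_score_of_cuts <- function(values, class_labels, lambda, cut_points) {
  keep <- !is.na(values)
  x <- values[keep]; y <- class_labels[keep] == "positive"
  bin <- findInterval(x, cut_points) + 1
  sc <- -length(cut_points) * log(lambda)
  for (b in unique(bin)) {
    np <- sum(y[bin == b]); nn <- sum(!y[bin == b])
    sc <- sc + lgamma(np + 1) + lgamma(nn + 1) - lgamma(np + nn + 2)
  }
  sc
}

# Pairwise Mann-Whitney AUC oracle: explicit loop over positive-negative
# pairs, ties counted one half.
oracle_auc <- function(scores, labels) {
  pos <- which(labels == "positive"); neg <- which(labels != "positive")
  wins <- 0
  for (i in pos) for (j in neg) {
    if (scores[i] > scores[j]) wins <- wins + 1
    else if (scores[i] == scores[j]) wins <- wins + 0.5
  }
  wins / (length(pos) * length(neg))
}

# Small complete cohort builder for property tests.
make_cohort <- function(n, p, correlation = 0, positive_fraction = 0.35,
                        seed = 1, class_shift = 0) {
  vars <- do.call(variable_set, lapply(seq_len(p), function(j)
    variable_spec(paste0("v", j), mean = j, sd = j,
                  class_shift = class_shift)))
  generate_complete_table(n, vars, correlation, positive_fraction, seed)
}
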