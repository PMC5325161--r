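# Ordered probabilistic rule lists learned by separate-and-conquer beam
# search. Candidate conjunctions of (variable, bin) literals are scored by
# the log Beta-binomial marginal likelihood (uniform Beta(1,1) prior) of the
# two-group class split they induce on the residual training samples; a rule
# is accepted only if that split scores above the undivided residual. Each
# rule carries a Laplace-smoothed posterior pr_post = (n_correct+1)/(n_match+2).

rule_score <- function(pos_in, neg_in, pos_out, neg_out) {
  log_dm_marginal(pos_in, neg_in) + log_dm_marginal(pos_out, neg_out)
}

condition_key <- function(conds) {
  paste(vapply(conds, function(cn) paste(cn$variable, cn$bin, sep = "="),
               character(1)), collapse = " & ")
}

new_rule <- function(conditions, conclusion, n_match, n_correct) {
  list(conditions = conditions, conclusion = conclusion,
       n_match = n_match, n_correct = n_correct,
       pr_post = (n_correct + 1) / (n_match + 2))
}

#' Learn an ordered probabilistic ruleset
#'
#' Separate-and-conquer decision-list induction on a complete binned table:
#' a beam search over conjunctions of at most \code{max_conditions}
#' (variable, bin) literals proposes the rule whose induced class split has
#' the highest Bayesian score; if it beats leaving the residual undivided
#' the rule is appended (conclusion = majority class of the samples it
#' covers), its covered samples are removed, and the search repeats. The
#' list ends in a default rule concluding the residual majority class.
#' Rules whose removal does not reduce training accuracy are pruned once,
#' in reverse order, yielding the parsimonious ruleset. The procedure is
#' deterministic: score ties break lexicographically on (variable, bin).
#'
#' @param binned A complete \code{binned_table} (impute or delete first).
#' @param max_conditions Maximum literals per rule (default 3).
#' @param beam_width Beam width of the conjunction search (default 5).
#' @param seed Unused by the deterministic search; kept for interface
#'   stability.
#' @param prune If TRUE (default), apply the parsimonious pruning pass.
#' @return A \code{ruleset}: ordered \code{rules}, a \code{default_rule},
#'   and \code{variables_used}.
#' @export
learn_ruleset <- function(binned, max_conditions = 3, beam_width = 5,
                          seed = 1, prune = TRUE) {
  bins <- binned$bins
  if (anyNA(bins))
    stopf("binned table contains missing cells; impute or delete before rule learning")
  y <- binned$labels == "positive"
  n <- nrow(bins)
  # literal pool, lexicographic in (variable, bin index)
  lits <- list()
  for (v in colnames(bins)) {
    for (b in binned$scheme[[v]]$bin_labels) {
      lits[[length(lits) + 1]] <- list(variable = v, bin = b,
                                       match = bins[, v] == b)
    }
  }
  alive <- rep(TRUE, n)
  rules <- list()
  if (n >= 2) repeat {
    pos_tot <- sum(y[alive]); neg_tot <- sum(!y[alive])
    if (pos_tot + neg_tot == 0) break
    base_score <- log_dm_marginal(pos_tot, neg_tot)
    score_cand <- function(match) {
      m <- match & alive
      pin <- sum(y[m]); nin <- sum(!y[m])
      if (pin + nin == 0) return(-Inf)
      rule_score(pin, nin, pos_tot - pin, neg_tot - nin)
    }
    # beam over conjunctions
    beam <- list()
    for (li in seq_along(lits)) {
      sc <- score_cand(lits[[li]]$match)
      beam[[length(beam) + 1]] <- list(idx = li, match = lits[[li]]$match,
                                       score = sc)
    }
    beam <- beam[order(-vapply(beam, `[[`, numeric(1), "score"),
                       vapply(beam, function(b) b$idx[1], numeric(1)))]
    beam <- beam[seq_len(min(beam_width, length(beam)))]
    best <- beam[[1]]
    depth <- 1
    while (depth < max_conditions) {
      ext <- list()
      seen <- character(0)
      for (b in beam) {
        used_vars <- vapply(lits[b$idx], `[[`, character(1), "variable")
        for (li in seq_along(lits)) {
          if (lits[[li]]$variable %in% used_vars) next
          idx <- sort(c(b$idx, li))
          key <- paste(idx, collapse = ",")
          if (key %in% seen) next
          seen <- c(seen, key)
          match <- b$match & lits[[li]]$match
          ext[[length(ext) + 1]] <- list(idx = idx, match = match,
                                         score = score_cand(match))
        }
      }
      if (length(ext) == 0) break
      ext <- ext[order(-vapply(ext, `[[`, numeric(1), "score"),
                       vapply(ext, function(e) paste(sprintf("%04d", e$idx),
                                                     collapse = ","),
                              character(1)))]
      beam <- ext[seq_len(min(beam_width, length(ext)))]
      if (beam[[1]]$score > best$score + 1e-12) best <- beam[[1]]
      depth <- depth + 1
    }
    if (best$score <= base_score + 1e-12) break
    m <- best$match & alive
    pin <- sum(y[m]); nin <- sum(!y[m])
    conclusion <- if (pin >= nin) "positive" else "non-positive"
    n_correct <- if (conclusion == "positive") pin else nin
    conds <- lapply(lits[best$idx],
                    function(l) list(variable = l$variable, bin = l$bin))
    rules[[length(rules) + 1]] <- new_rule(conds, conclusion, pin + nin,
                                           n_correct)
    rules[[length(rules)]]$match <- best$match  # full-data match, for pruning
    alive <- alive & !m
    if (!any(alive)) break
  }
  pos_res <- sum(y[alive]); neg_res <- sum(!y[alive])
  def_cls <- if (pos_res > neg_res) "positive" else if (neg_res > pos_res)
    "non-positive" else if (sum(y) > sum(!y)) "positive" else "non-positive"
  def_cor <- if (def_cls == "positive") pos_res else neg_res
  default_rule <- new_rule(list(), def_cls, pos_res + neg_res, def_cor)
  rs <- structure(list(rules = rules, default_rule = default_rule,
                       variables_used = character(0)),
                  class = "ruleset")
  if (prune && length(rules) > 0) rs <- prune_ruleset(rs, binned)
  rs$rules <- lapply(rs$rules, function(r) { r$match <- NULL; r })
  rs$variables_used <- sort(unique(unlist(lapply(rs$rules, function(r)
    vapply(r$conditions, `[[`, character(1), "variable")))))
  rs
}

# Parsimonious pass: drop rules (reverse order, one sweep) whose deletion
# does not reduce training accuracy.
prune_ruleset <- function(ruleset, binned) {
  acc <- function(rs) {
    pred <- predict(rs, binned)$class
    mean(pred == binned$labels)
  }
  base <- acc(ruleset)
  for (i in rev(seq_along(ruleset$rules))) {
    trial <- ruleset
    trial$rules[[i]] <- NULL
    a <- acc(trial)
    if (a >= base - 1e-12) {
      ruleset <- trial
      base <- a
    }
  }
  ruleset
}

rule_matches_row <- function(rule, row) {
  for (cn in rule$conditions) {
    if (is.na(row[[cn$variable]]) || row[[cn$variable]] != cn$bin)
      return(FALSE)
  }
  TRUE
}

#' Score samples with a ruleset
#'
#' The first rule (in list order) whose conditions a sample satisfies
#' determines the prediction; the default rule matches everything. The score
#' is the firing rule's posterior for positive conclusions and
#' \code{1 - pr_post} for non-positive conclusions, so it always reads as
#' the probability of the positive class.
#'
#' @param object A \code{ruleset}.
#' @param binned A complete \code{binned_table} (or a single named row).
#' @param ... Unused.
#' @return A data frame with \code{class}, \code{score}, \code{rule} (index
#'   of the firing rule; 0 = default) per sample.
#' @export
predict.ruleset <- function(object, binned, ...) {
  bins <- if (inherits(binned, "binned_table")) binned$bins else
    matrix(unlist(binned), nrow = 1, dimnames = list(NULL, names(binned)))
  if (anyNA(bins)) stopf("samples contain missing bins; impute first")
  n <- nrow(bins)
  out <- data.frame(class = character(n), score = numeric(n),
                    rule = integer(n), stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    row <- as.list(bins[i, ])
    fired <- 0L
    rule <- object$default_rule
    for (j in seq_along(object$rules)) {
      if (rule_matches_row(object$rules[[j]], row)) {
        fired <- j
        rule <- object$rules[[j]]
        break
      }
    }
    out$class[i] <- rule$conclusion
    out$score[i] <- if (rule$conclusion == "positive") rule$pr_post else
      1 - rule$pr_post
    out$rule[i] <- fired
  }
  out
}

#' @export
print.ruleset <- function(x, ...) {
  cat(sprintf("ruleset: %d rules + default, variables used: %s\n",
              length(x$rules),
              if (length(x$variables_used)) paste(x$variables_used,
                                                  collapse = ", ") else "none"))
  cat(format_ruleset(x), sep = "\n")
  invisible(x)
}

#' Render a ruleset as human-readable text
#'
#' @param ruleset A \code{ruleset}.
#' @return Character vector, one line per rule, in
#'   \code{"IF var = bin AND ... THEN class (pr_post)"} form.
#' @export
format_ruleset <- function(ruleset) {
  fmt <- function(r, i) {
    cond <- if (length(r$conditions) == 0) "TRUE" else
      paste(vapply(r$conditions, function(cn)
        sprintf("%s = %s", cn$variable, cn$bin), character(1)),
        collapse = " AND ")
    sprintf("%d. IF %s THEN %s (%.3f, %d/%d)", i, cond, r$conclusion,
            r$pr_post, r$n_correct, r$n_match)
  }
  body <- if (length(ruleset$rules) > 0)
    vapply(seq_along(ruleset$rules),
           function(i) fmt(ruleset$rules[[i]], i), character(1))
  else character(0)
  c(body, fmt(ruleset$default_rule, length(ruleset$rules) + 1))
}
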