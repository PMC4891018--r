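# RECursive Partitioning and AMalgamation for censored outcomes.
#
# Growth: at each node, candidate binary splits (midpoints of adjacent
# observed values of each splitting variable) are screened by the two-sample
# log-rank statistic, the best few refined by the likelihood-ratio
# improvement of a Weibull PH model containing the split indicator plus any
# global adjustment covariates, and the winning split accepted only if its
# maximally-selected statistic clears a Lausen-Schumacher-corrected
# significance level (a raw AIC comparison cannot see the cut-point search
# and would split pure noise).  Pruning: weakest-link collapse to the
# subtree whose terminal-class Weibull model minimises total AIC.
# Amalgamation: terminal nodes with non-significant pairwise hazard-ratio
# contrasts are merged; classes are ordered by fitted risk, class 1 the
# highest, the lowest-risk class being the reference (HR = 1).

# improved-Bonferroni p-value for a maximally selected chi-square(1)
# statistic searched over cut quantiles [eps1, eps2] (Lausen & Schumacher)
ls_corrected_p <- function(stat, eps1, eps2) {
  if (!is.finite(stat) || stat <= 1) return(1)
  b <- sqrt(stat)
  rho <- (eps2 * (1 - eps1)) / (eps1 * (1 - eps2))
  p <- dnorm(b) * (b - 1 / b) * log(rho) + 4 * dnorm(b) / b
  min(max(p, pchisq(stat, 1, lower.tail = FALSE)), 1)
}

# vectorised log-rank statistic over all candidate cuts of one variable
logrank_all_cuts <- function(time, event, x, cuts, min_node_events) {
  tau <- sort(unique(time[event == 1]))
  if (!length(tau) || !length(cuts)) {
    return(rep(NA_real_, length(cuts)))
  }
  A <- outer(time, tau, ">=")                     # at risk
  E <- outer(time, tau, "==") & (event == 1)      # event at tau_j
  M <- outer(x, cuts, "<=")                       # goes left
  n_j <- colSums(A)
  d_j <- colSums(E)
  n1 <- crossprod(M, A)                           # cuts x times
  d1 <- crossprod(M, E)
  frac <- sweep(n1, 2, n_j, "/")
  o_minus_e <- rowSums(d1) - drop(frac %*% d_j)
  vfac <- ifelse(n_j > 1, d_j * (n_j - d_j) / (n_j - 1), 0)
  v <- drop((frac * (1 - frac)) %*% vfac)
  stat <- ifelse(v > 0, o_minus_e^2 / v, NA_real_)
  # admissibility: enough events on both sides
  ev_left <- drop(crossprod(M, event))
  inadmissible <- ev_left < min_node_events |
    (sum(event) - ev_left) < min_node_events
  stat[inadmissible] <- NA_real_
  stat
}

candidate_cuts <- function(x, max_cuts) {
  ux <- sort(unique(x))
  if (length(ux) < 2) return(numeric(0))
  cuts <- (ux[-1] + ux[-length(ux)]) / 2
  if (length(cuts) > max_cuts) {
    cuts <- unique(quantile(cuts, probs = seq(0, 1, length.out = max_cuts),
                            names = FALSE, type = 1))
  }
  cuts
}

# Weibull log-likelihood of a node model: globals (+ optional indicator)
node_loglik <- function(time, event, G, indicator = NULL) {
  X <- G
  if (!is.null(indicator)) X <- cbind(X, split = indicator)
  res <- weibull_ph_newton(time, event, X)
  if (!res$converged) return(NA_real_)
  res$loglik
}

find_best_split <- function(time, event, Xs, G, min_node_events, max_cuts,
                            top_k = 5L) {
  screened <- list()
  for (v in colnames(Xs)) {
    cuts <- candidate_cuts(Xs[, v], max_cuts)
    if (!length(cuts)) next
    stat <- logrank_all_cuts(time, event, Xs[, v], cuts, min_node_events)
    ok <- which(is.finite(stat))
    if (length(ok)) {
      screened[[v]] <- tibble(var = v, cut = cuts[ok], logrank = stat[ok],
                              prop_left = purrr::map_dbl(cuts[ok], ~ mean(Xs[, v] <= .x)))
    }
  }
  if (!length(screened)) return(NULL)
  cand <- dplyr::bind_rows(screened)
  eps1 <- min(cand$prop_left)
  eps2 <- max(cand$prop_left)
  top <- dplyr::slice_max(cand, .data$logrank, n = top_k, with_ties = FALSE)
  ll_null <- node_loglik(time, event, G)
  if (!is.finite(ll_null)) return(NULL)
  best <- NULL
  for (k in seq_len(nrow(top))) {
    ind <- as.numeric(Xs[, top$var[k]] <= top$cut[k])
    ll_alt <- node_loglik(time, event, G, ind)
    if (!is.finite(ll_alt)) next
    lr <- 2 * (ll_alt - ll_null)
    if (is.null(best) || lr > best$lr) {
      best <- list(var = top$var[k], cut = top$cut[k], lr = lr)
    }
  }
  if (is.null(best)) return(NULL)
  best$p_corrected <- ls_corrected_p(best$lr, max(eps1, 1e-3), min(eps2, 1 - 1e-3))
  best
}

#' Fit a RECPAM survival tree
#'
#' Recursive partitioning and amalgamation of a censored cohort into ordered
#' risk classes, with splits evaluated through Weibull-modelled hazard
#' ratios.  See the package vignette for the concrete algorithm (split
#' screening, corrected split-selection test, AIC pruning, pairwise-HR
#' amalgamation).
#'
#' @param data Cohort data frame (no missing values among the variables
#'   used).
#' @param splitting_vars Numeric columns searched for binary cuts; patients
#'   with values at or below a cut go left.
#' @param global_vars Adjustment covariates included in every node model and
#'   in the final class model.
#' @param time_col,event_col Outcome columns.
#' @param min_node_events Minimum events required on each side of a split
#'   (default 3).
#' @param alpha_split Significance level for the corrected split-selection
#'   test (default 0.05).
#' @param alpha_amalg Significance level below which two terminal classes
#'   are kept apart during amalgamation (default 0.05).
#' @param max_cuts Cap on candidate cut-points per variable per node
#'   (default 64; quantile-thinned above that).
#' @param max_depth Maximum tree depth (default 8).
#' @return An object of class `recpam_tree`: `nodes` (split structure with
#'   per-node events / non-events), `classes` (per-class n, events, HR vs
#'   the lowest-risk reference with 95% Wald CI and p-value), patient
#'   `assignments`, the `aic_trace` over subtree sizes, and the final class
#'   `fit`.  A cohort with no admissible or significant split returns a
#'   single-class tree.
#' @export
fit_recpam <- function(data, splitting_vars, global_vars = character(),
                       time_col = "time_years", event_col = "event",
                       min_node_events = 3, alpha_split = 0.05,
                       alpha_amalg = 0.05, max_cuts = 64, max_depth = 8) {
  check_outcome(data, time_col, event_col)
  if (!length(splitting_vars)) stop_invalid("At least one splitting variable is required.")
  check_covariates_present(data, c(splitting_vars, global_vars))
  if (sum(data[[event_col]]) < 2) stop_invalid("At least two events are required.")
  used <- unique(c(splitting_vars, global_vars))
  if (anyNA(data[used])) stop_invalid("Missing values among tree variables; impute or drop first.")

  time <- data[[time_col]]
  event <- data[[event_col]]
  n <- length(time)
  Xs <- as.matrix(data[splitting_vars])
  G <- if (length(global_vars)) as.matrix(data[global_vars]) else NULL

  nodes <- list()
  new_node <- function(idx, parent, depth) {
    id <- length(nodes) + 1L
    nodes[[id]] <<- list(
      id = id, parent = parent, depth = depth, idx = idx,
      n = length(idx), events = sum(event[idx]),
      split_var = NA_character_, cut = NA_real_, lr = NA_real_,
      left = NA_integer_, right = NA_integer_
    )
    id
  }
  grow <- function(id) {
    nd <- nodes[[id]]
    if (nd$depth >= max_depth || nd$events < 2 * min_node_events) return(invisible())
    idx <- nd$idx
    best <- find_best_split(
      time[idx], event[idx], Xs[idx, , drop = FALSE],
      if (is.null(G)) NULL else G[idx, , drop = FALSE],
      min_node_events, max_cuts
    )
    if (is.null(best) || best$p_corrected >= alpha_split) return(invisible())
    left_idx <- idx[Xs[idx, best$var] <= best$cut]
    right_idx <- setdiff(idx, left_idx)
    lid <- new_node(left_idx, id, nd$depth + 1L)
    rid <- new_node(right_idx, id, nd$depth + 1L)
    nodes[[id]]$split_var <<- best$var
    nodes[[id]]$cut <<- best$cut
    nodes[[id]]$lr <<- best$lr
    nodes[[id]]$left <<- lid
    nodes[[id]]$right <<- rid
    grow(lid)
    grow(rid)
    invisible()
  }
  root <- new_node(seq_len(n), NA_integer_, 0L)
  grow(root)

  is_split <- function(id) !is.na(nodes[[id]]$split_var)
  terminals_of <- function(collapsed) {
    # leaves of the tree once nodes in `collapsed` are treated as terminal
    out <- integer(0)
    walk <- function(id) {
      if (!is_split(id) || id %in% collapsed) {
        out <<- c(out, id)
      } else {
        walk(nodes[[id]]$left)
        walk(nodes[[id]]$right)
      }
    }
    walk(root)
    out
  }

  # model over groups of patients: membership list -> fit with indicators
  fit_groups <- function(groups) {
    if (length(groups) <= 1) {
      return(fit_weibull_ph(data, global_vars, time_col, event_col))
    }
    dat <- data
    ind_names <- character(0)
    for (k in seq_along(groups)[-1]) {
      nm <- paste0(".grp_", k)
      dat[[nm]] <- as.numeric(seq_len(n) %in% groups[[k]])
      ind_names <- c(ind_names, nm)
    }
    fit_weibull_ph(dat, c(ind_names, global_vars), time_col, event_col)
  }

  # -- pruning: weakest-link sequence, minimum class-model AIC ------------
  collapsed <- integer(0)
  seqs <- list(list(collapsed = collapsed))
  repeat {
    terms <- terminals_of(collapsed)
    # internal nodes whose two children are both terminal under `collapsed`
    cands <- purrr::keep(seq_along(nodes), function(id) {
      is_split(id) && !id %in% collapsed &&
        all(c(nodes[[id]]$left, nodes[[id]]$right) %in% terms)
    })
    if (!length(cands)) break
    weakest <- cands[which.min(purrr::map_dbl(cands, ~ nodes[[.x]]$lr))]
    collapsed <- c(collapsed, weakest)
    seqs[[length(seqs) + 1L]] <- list(collapsed = collapsed)
  }
  aic_trace <- purrr::map_dfr(seqs, function(s) {
    terms <- terminals_of(s$collapsed)
    f <- tryCatch(
      suppressWarnings(fit_groups(purrr::map(terms, ~ nodes[[.x]]$idx))),
      error = function(e) NULL
    )
    tibble(n_terminals = length(terms),
           aic = if (is.null(f)) NA_real_ else f$aic)
  })
  ok <- which(is.finite(aic_trace$aic))
  # smallest tree among AIC minimisers
  best_i <- ok[order(aic_trace$aic[ok], aic_trace$n_terminals[ok])][1]
  collapsed <- seqs[[best_i]]$collapsed
  terms <- terminals_of(collapsed)

  # -- amalgamation: merge terminal groups with non-significant HR contrast
  groups <- purrr::map(terms, ~ nodes[[.x]]$idx)
  members <- purrr::map(seq_along(terms), ~ terms[.x]) # node ids per class
  repeat {
    if (length(groups) <= 1) break
    f <- suppressWarnings(fit_groups(groups))
    est <- c(0, f$coefficients[paste0(".grp_", seq_along(groups)[-1])])
    V <- matrix(0, length(groups), length(groups))
    nm <- paste0(".grp_", seq_along(groups)[-1])
    V[-1, -1] <- f$vcov[nm, nm, drop = FALSE]
    worst <- NULL
    for (a in seq_along(groups)) {
      for (b in seq_len(a - 1)) {
        se <- sqrt(max(V[a, a] + V[b, b] - 2 * V[a, b], 0))
        p <- if (se > 0) 2 * pnorm(-abs(est[a] - est[b]) / se) else 0
        if (is.null(worst) || p > worst$p) worst <- list(a = a, b = b, p = p)
      }
    }
    if (worst$p <= alpha_amalg) break
    groups[[worst$b]] <- sort(c(groups[[worst$b]], groups[[worst$a]]))
    members[[worst$b]] <- c(members[[worst$b]], members[[worst$a]])
    groups[[worst$a]] <- NULL
    members[[worst$a]] <- NULL
  }

  # -- order classes by fitted risk; refit with lowest-risk reference ----
  if (length(groups) > 1) {
    f0 <- suppressWarnings(fit_groups(groups))
    est <- c(0, unname(f0$coefficients[paste0(".grp_", seq_along(groups)[-1])]))
    ord <- order(est, decreasing = TRUE) # class 1 = highest risk
    groups <- groups[ord]
    members <- members[ord]
    ref_last <- c(seq_along(groups)[-1], 1L)
    # refit with the reference (lowest risk) as the baseline group
    groups_ref <- c(groups[length(groups)], groups[-length(groups)])
    f <- suppressWarnings(fit_groups(groups_ref))
    # groups_ref[1] = reference; coefficient .grp_k corresponds to class k-1
    k <- length(groups)
    est <- unname(f$coefficients[paste0(".grp_", seq_len(k)[-1])])
    se <- f$wald$std.error[match(paste0(".grp_", seq_len(k)[-1]), f$wald$term)]
    hr <- c(exp(est), 1)
    lo <- c(exp(est - 1.96 * se), 1)
    hi <- c(exp(est + 1.96 * se), 1)
    pv <- c(2 * pnorm(-abs(est / se)), NA_real_)
    final_fit <- f
  } else {
    final_fit <- suppressWarnings(fit_groups(groups))
    hr <- 1; lo <- 1; hi <- 1; pv <- NA_real_
  }

  root_fit <- suppressWarnings(fit_weibull_ph(data, global_vars, time_col, event_col))
  if (length(groups) > 1 && final_fit$aic > root_fit$aic) {
    # safety net: a class structure must not fit worse than no structure
    groups <- list(seq_len(n))
    members <- list(terminals_of(seq_along(nodes)))
    final_fit <- root_fit
    hr <- 1; lo <- 1; hi <- 1; pv <- NA_real_
  }

  assignments <- integer(n)
  for (k in seq_along(groups)) assignments[groups[[k]]] <- k
  node_class <- integer(length(nodes))
  for (k in seq_along(members)) node_class[members[[k]]] <- k

  classes <- tibble(
    class = seq_along(groups),
    n = purrr::map_int(groups, length),
    events = purrr::map_int(groups, ~ sum(event[.x])),
    hr = hr, conf_low = lo, conf_high = hi, p_value = pv,
    reference = seq_along(groups) == length(groups)
  )

  nodes_tbl <- purrr::map_dfr(nodes, function(nd) {
    tibble(
      id = nd$id, parent = nd$parent, depth = nd$depth,
      n = nd$n, events = nd$events, non_events = nd$n - nd$events,
      split_var = nd$split_var, cut = nd$cut, lr = nd$lr,
      left = nd$left, right = nd$right
    )
  })

  structure(
    list(
      nodes = nodes_tbl,
      tree = nodes,
      collapsed = collapsed,
      root = root,
      node_class = node_class,
      classes = classes,
      assignments = assignments,
      aic_trace = aic_trace,
      fit = final_fit,
      aic = final_fit$aic,
      root_aic = root_fit$aic,
      splitting_vars = splitting_vars,
      global_vars = global_vars,
      params = list(min_node_events = min_node_events,
                    alpha_split = alpha_split, alpha_amalg = alpha_amalg,
                    max_cuts = max_cuts, max_depth = max_depth),
      time_col = time_col, event_col = event_col
    ),
    class = "recpam_tree"
  )
}

get_ancestors <- function(nodes, id) {
  out <- integer(0)
  while (!is.na(nodes[[id]]$parent)) {
    id <- nodes[[id]]$parent
    out <- c(out, id)
  }
  out
}

#' Classify patients with a RECPAM tree
#'
#' Routes each row down the tree: values at or below a split's cut-point go
#' left, strictly greater go right (so a score exactly at a class boundary
#' falls in the lower-risk class, as in "score <= 0.50 is the reference
#' class").
#'
#' @param object A `recpam_tree`.
#' @param newdata Data frame with the tree's splitting variables.
#' @param ... Unused.
#' @return Integer vector of class labels (1 = highest risk).
#' @export
predict.recpam_tree <- function(object, newdata, ...) {
  vars_needed <- unique(stats::na.omit(object$nodes$split_var[
    !object$nodes$id %in% object$collapsed
  ]))
  check_covariates_present(newdata, vars_needed)
  if (anyNA(newdata[vars_needed])) {
    stop_invalid("Missing values in split variables; cannot route patients.")
  }
  nodes <- object$tree
  route <- function(i) {
    id <- object$root
    repeat {
      nd <- nodes[[id]]
      if (is.na(nd$split_var) || id %in% object$collapsed) {
        return(object$node_class[id])
      }
      id <- if (newdata[[nd$split_var]][i] <= nd$cut) nd$left else nd$right
    }
  }
  vapply(seq_len(nrow(newdata)), route, integer(1))
}

#' Build a RECPAM-style classification tree from fixed cut-offs
#'
#' Constructs the right-cascading tree implied by ordered cut-offs on a
#' single score: values at or below the first cut form the lowest-risk
#' (reference) class, values above the last cut the highest-risk class 1.
#' Useful for applying published risk-class boundaries to new patients.
#'
#' @param variable Score column name.
#' @param cuts Increasing numeric cut-offs.
#' @return A `recpam_tree` carrying only the classification structure
#'   (class HRs are `NA`: no data were fitted).
#' @examples
#' tree <- recpam_tree_from_cuts("mrs", c(0.50, 0.88))
#' predict(tree, data.frame(mrs = c(0.50, 0.70, 0.89)))
#' @export
recpam_tree_from_cuts <- function(variable, cuts) {
  if (is.unsorted(cuts, strictly = TRUE)) {
    stop_invalid("`cuts` must be strictly increasing.")
  }
  k <- length(cuts) + 1L # number of classes
  nodes <- list()
  for (i in seq_along(cuts)) {
    id <- 2L * i - 1L
    nodes[[id]] <- list(id = id, parent = if (i == 1) NA_integer_ else 2L * i - 3L,
                        depth = i - 1L, idx = integer(0), n = 0L, events = 0L,
                        split_var = variable, cut = cuts[i],
                        lr = NA_real_, left = 2L * i, right = 2L * i + 1L)
    nodes[[2L * i]] <- list(id = 2L * i, parent = id, depth = i, idx = integer(0),
                            n = 0L, events = 0L, split_var = NA_character_,
                            cut = NA_real_, lr = NA_real_,
                            left = NA_integer_, right = NA_integer_)
  }
  last <- 2L * length(cuts) + 1L
  nodes[[last]] <- list(id = last, parent = 2L * length(cuts) - 1L,
                        depth = length(cuts), idx = integer(0), n = 0L,
                        events = 0L, split_var = NA_character_, cut = NA_real_,
                        lr = NA_real_, left = NA_integer_, right = NA_integer_)
  node_class <- integer(length(nodes))
  # left terminal of split i gets class k - i + 1 (leftmost = reference = k)
  for (i in seq_along(cuts)) node_class[2L * i] <- k - i + 1L
  node_class[last] <- 1L
  structure(
    list(
      nodes = purrr::map_dfr(nodes, ~ tibble(
        id = .x$id, parent = .x$parent, depth = .x$depth, n = .x$n,
        events = .x$events, non_events = 0L, split_var = .x$split_var,
        cut = .x$cut, lr = .x$lr, left = .x$left, right = .x$right
      )),
      tree = nodes, collapsed = integer(0), root = 1L,
      node_class = node_class,
      classes = tibble(class = seq_len(k), n = NA_integer_,
                       events = NA_integer_, hr = NA_real_,
                       conf_low = NA_real_, conf_high = NA_real_,
                       p_value = NA_real_, reference = seq_len(k) == k),
      assignments = integer(0), aic_trace = tibble(), fit = NULL,
      aic = NA_real_, root_aic = NA_real_,
      splitting_vars = variable, global_vars = character(0),
      params = list(), time_col = NA_character_, event_col = NA_character_
    ),
    class = "recpam_tree"
  )
}

#' Check whether metabolite effects are adequately additive
#'
#' Compares the AIC of the additive multivariable Weibull model against a
#' RECPAM tree grown with the same metabolites as both global and splitting
#' variables.  When the tree offers no AIC improvement, the additive model
#' is judged adequate (no interaction structure worth modelling).
#'
#' @param data Cohort data frame.
#' @param metabolites Metabolite columns.
#' @param ... Passed on to [fit_recpam()].
#' @inheritParams fit_recpam
#' @return A one-row tibble: verdict (`"additive adequate"` /
#'   `"tree improves"`), the two AICs, the AIC improvement, and the number
#'   of tree classes.
#' @export
interaction_check <- function(data, metabolites,
                              time_col = "time_years", event_col = "event", ...) {
  if (!length(metabolites)) stop_invalid("`metabolites` must not be empty.")
  additive <- fit_weibull_ph(data, metabolites, time_col, event_col)
  tree <- fit_recpam(data, splitting_vars = metabolites,
                     global_vars = metabolites,
                     time_col = time_col, event_col = event_col, ...)
  improvement <- additive$aic - tree$aic
  tibble(
    verdict = if (improvement > 0) "tree improves" else "additive adequate",
    aic_additive = additive$aic,
    aic_tree = tree$aic,
    improvement = improvement,
    n_classes = nrow(tree$classes)
  )
}

#' @export
print.recpam_tree <- function(x, ...) {
  cat("RECPAM survival tree\n")
  cat(sprintf("  %d class(es); final AIC %.3f (root-only %.3f)\n",
              nrow(x$classes), x$aic, x$root_aic))
  render <- function(id, indent) {
    nd <- x$tree[[id]]
    pad <- strrep("  ", indent)
    counts <- sprintf("[%d ev / %d non-ev]", nd$events, nd$n - nd$events)
    if (is.na(nd$split_var) || id %in% x$collapsed) {
      cls <- x$node_class[id]
      ref <- if (length(cls) && isTRUE(x$classes$reference[match(cls, x$classes$class)])) " (reference)" else ""
      cat(sprintf("%s* class %s %s%s\n", pad, cls, counts, ref))
    } else {
      cat(sprintf("%s%s <= %.4g? %s\n", pad, nd$split_var, nd$cut, counts))
      render(nd$left, indent + 1)
      render(nd$right, indent + 1)
    }
  }
  if (length(x$tree)) render(x$root, 1)
  if (nrow(x$classes) && !all(is.na(x$classes$hr))) print(x$classes)
  invisible(x)
}

#' @method tidy recpam_tree
#' @export
tidy.recpam_tree <- function(x, ...) x$classes

#' @method glance recpam_tree
#' @export
glance.recpam_tree <- function(x, ...) {
  tibble(n_classes = nrow(x$classes), AIC = x$aic, root_AIC = x$root_aic)
}

#' Serialize a RECPAM tree to JSON
#'
#' @param tree A `recpam_tree`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return `path` invisibly, or the JSON string.
#' @export
recpam_to_json <- function(tree, path = NULL) {
  payload <- list(
    format = "mrscore_recpam_tree", version = 1L,
    root = tree$root,
    collapsed = tree$collapsed,
    node_class = tree$node_class,
    nodes = tree$nodes,
    classes = tree$classes,
    splitting_vars = tree$splitting_vars,
    global_vars = tree$global_vars
  )
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(path)
}
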