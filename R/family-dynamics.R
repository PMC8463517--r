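# Birth-death modelling of gene family size change along a dated species
# tree: the equal-rates linear birth-death transition kernel, pruning
# likelihood, global rate estimation, ancestral family sizes with
# per-branch expansion / contraction, and Monte-Carlo family p-values.

#' Transition probability of the equal-rates linear birth-death process
#'
#' Probability that a family of `s` genes becomes `c` genes after time
#' `t` when each gene is gained and lost at the same rate `lambda`:
#' with \eqn{\alpha = \lambda t / (1 + \lambda t)},
#' \deqn{P(c \mid s, t) = \sum_{j=0}^{\min(s,c)} \binom{s}{j}
#'   \binom{s+c-j-1}{s-1} \alpha^{s+c-2j} (1-2\alpha)^j.}
#' Zero genes is absorbing; at `t = 0` (or `lambda = 0`) the kernel is
#' the identity.
#'
#' @param s Parent count (non-negative integer).
#' @param c Child count(s); vectorised.
#' @param t Elapsed time, non-negative.
#' @param lambda Per-gene gain/loss rate, non-negative.
#' @return Probability vector, same length as `c`.
#' @export
bdp_transition_prob <- function(s, c, t, lambda) {
  stopifnot(s >= 0, t >= 0, lambda >= 0, all(c >= 0))
  if (t == 0 || lambda == 0) return(as.numeric(c == s))
  if (s == 0) return(as.numeric(c == 0))
  # the closed form (alternating sum over j) cancels badly for large s;
  # compute instead as the s-fold convolution of the single-gene
  # offspring law P(0) = alpha, P(k) = (1-alpha)^2 alpha^(k-1) -- an
  # algebraically identical, all-positive formulation
  N <- max(c)
  row <- bdp_row(s, lambda * t, N)
  row[c + 1L]
}

# P(c | s) for c = 0..N under the equal-rates kernel, by convolution
bdp_row <- function(s, lt, N) {
  alpha <- lt / (1 + lt)
  p1 <- c(alpha, (1 - alpha)^2 * alpha^(0:max(N - 1, 0)))[1:(N + 1)]
  row <- p1
  if (s > 1) {
    for (i in 2:s) {
      new <- numeric(N + 1)
      for (k in 0:N) {
        if (row[k + 1] > 0) {
          idx <- k + 0:(N - k)
          new[idx + 1] <- new[idx + 1] + row[k + 1] * p1[1:(N - k + 1)]
        }
      }
      row <- new
    }
  }
  row
}

# (max+1) x (max+1) transition matrix, rows s = 0..max, truncated at max
bdp_transition_matrix <- function(t, lambda, max_count) {
  key <- paste("bdpT", signif(t, 12), signif(lambda, 12), max_count, sep = "_")
  if (!is.null(the[[key]])) return(the[[key]])
  n <- max_count + 1L
  Tm <- matrix(0, n, n)
  if (t == 0 || lambda == 0) {
    diag(Tm) <- 1
  } else {
    # successive convolutions share work across rows: row for s parents
    # is row for s-1 convolved once more with the single-gene law
    alpha <- lambda * t / (1 + lambda * t)
    N <- max_count
    p1 <- c(alpha, (1 - alpha)^2 * alpha^(0:max(N - 1, 0)))[1:(N + 1)]
    Tm[1, 1] <- 1
    row <- p1
    Tm[2, ] <- row
    if (max_count >= 2) {
      for (s in 2:max_count) {
        new <- numeric(N + 1)
        for (k in 0:N) {
          if (row[k + 1] > 0) {
            idx <- k + 0:(N - k)
            new[idx + 1] <- new[idx + 1] + row[k + 1] * p1[1:(N - k + 1)]
          }
        }
        row <- new
        Tm[s + 1, ] <- row
      }
    }
  }
  the[[key]] <- Tm
  Tm
}

# profiles: tibble with family_id column + one integer column per species
profile_counts <- function(profiles, i, species) {
  stats::setNames(as.numeric(profiles[i, species]), species)
}

check_ultrametric <- function(tree, tol = 1e-6) {
  depths <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  if (diff(range(depths)) > tol) warning("tree is not ultrametric")
  invisible(tree)
}

# pruning partials for one family: list with L (matrix nodes x states)
bdp_prune <- function(counts, tree, lambda, max_count) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  states <- 0:max_count
  L <- matrix(1, nrow = nn, ncol = max_count + 1L)
  for (i in seq_len(ntip)) {
    cnt <- counts[[tree$tip.label[i]]]
    if (is.null(cnt) || is.na(cnt)) next  # missing species: uninformative
    if (cnt > max_count) stop("tip count ", cnt, " exceeds max_count")
    L[i, ] <- 0
    L[i, cnt + 1L] <- 1
  }
  tree <- stats::reorder(tree, "cladewise")
  ord <- rev(unique(tree$edge[, 1]))
  msg <- matrix(1, nrow = nn, ncol = max_count + 1L)  # T_child %*% L_child per child
  for (nd in ord) {
    es <- which(tree$edge[, 1] == nd)
    acc <- rep(1, max_count + 1L)
    for (e in es) {
      kid <- tree$edge[e, 2]
      Tm <- bdp_transition_matrix(tree$edge.length[e], lambda, max_count)
      m <- as.vector(Tm %*% L[kid, ])
      msg[kid, ] <- m
      acc <- acc * m
    }
    L[nd, ] <- acc
  }
  list(L = L, msg = msg, states = states)
}

#' Birth-death log-likelihood of a family-size profile
#'
#' Felsenstein pruning over family sizes 0..`max_count` with the
#' birth-death transition kernel on each branch; the root size is
#' marginalised uniformly over 1..`max_count` (conditioning on at least
#' one ancestral gene).
#'
#' @param counts Named vector of tip counts (names = tip labels), or a
#'   one-row slice of a family profile table.
#' @param tree Ultrametric `phylo` with branch lengths in time units.
#' @param lambda Gain/loss rate.
#' @param max_count State-space truncation (default 100).
#' @return Log-likelihood.
#' @export
family_loglik <- function(counts, tree, lambda, max_count = 100) {
  counts <- as.list(counts)
  pr <- bdp_prune(counts, tree, lambda, max_count)
  root <- length(tree$tip.label) + 1L
  log(mean(pr$L[root, -1L]))
}

#' Estimate the global birth-death rate by maximum likelihood
#'
#' One-dimensional MLE of a single lambda shared by all branches and
#' families, searched on log-lambda over \[1e-6, 1\].
#'
#' @param profiles Tibble: `family_id` plus one count column per species.
#' @param tree Ultrametric `phylo`; tip labels must cover the species
#'   columns.
#' @param max_count State-space truncation (default 100).
#' @param tol Optimiser tolerance on log-lambda (default 1e-4).
#' @return Estimated rate (warns when the estimate sits at the search
#'   boundary).
#' @export
estimate_lambda <- function(profiles, tree, max_count = 100, tol = 1e-4) {
  if (nrow(profiles) < 10) stop("need at least 10 families")
  species <- setdiff(names(profiles), "family_id")
  stopifnot(all(species %in% tree$tip.label))
  negll <- function(loglam) {
    lam <- exp(loglam)
    -sum(vapply(seq_len(nrow(profiles)), function(i) {
      family_loglik(profile_counts(profiles, i, species), tree, lam, max_count)
    }, numeric(1)))
  }
  opt <- stats::optimize(negll, interval = log(c(1e-6, 1)), tol = tol)
  lam <- exp(opt$minimum)
  if (opt$minimum < log(1e-6) + 2 * tol || opt$minimum > log(1) - 2 * tol) {
    warning("lambda estimate at search boundary")
  }
  lam
}

#' Ancestral family sizes and per-branch change
#'
#' Reconstructs the maximum-posterior family size at every internal node
#' from the pruning tables (ties toward the smaller count), reports the
#' per-branch change (child minus parent) for every family, and the
#' per-species average expansion (mean change on each terminal branch
#' across families).
#'
#' @inheritParams estimate_lambda
#' @param lambda Gain/loss rate.
#' @return An `nlr_bdp` object: `branch_deltas` tibble (family_id,
#'   parent, child, child_label, delta), `average_expansion` tibble
#'   (species, average_expansion), `root_states` tibble. `tidy()`
#'   returns `branch_deltas`, `glance()` the per-species averages in
#'   wide form.
#' @export
branch_changes <- function(profiles, tree, lambda, max_count = 100) {
  species <- setdiff(names(profiles), "family_id")
  stopifnot(all(species %in% tree$tip.label))
  tree <- stats::reorder(tree, "cladewise")
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  nn <- ntip + tree$Nnode
  prior <- c(0, rep(1 / max_count, max_count))

  deltas <- purrr::map_dfr(seq_len(nrow(profiles)), function(i) {
    counts <- profile_counts(profiles, i, species)
    pr <- bdp_prune(as.list(counts), tree, lambda, max_count)
    # downward messages
    D <- matrix(0, nrow = nn, ncol = max_count + 1L)
    D[root, ] <- prior
    for (e in seq_len(nrow(tree$edge))) {  # cladewise order = preorder
      par <- tree$edge[e, 1]; kid <- tree$edge[e, 2]
      sibs <- setdiff(tree$edge[tree$edge[, 1] == par, 2], kid)
      up <- D[par, ]
      for (w in sibs) up <- up * pr$msg[w, ]
      Tm <- bdp_transition_matrix(tree$edge.length[e], lambda, max_count)
      D[kid, ] <- as.vector(crossprod(Tm, up))
    }
    post <- pr$L * D
    map_state <- apply(post, 1, function(v) which.max(v) - 1L)  # ties: smaller
    # tips with observed counts are fixed
    for (k in seq_len(ntip)) {
      cnt <- counts[[tree$tip.label[k]]]
      if (!is.null(cnt) && !is.na(cnt)) map_state[k] <- cnt
    }
    tibble::tibble(
      family_id = profiles$family_id[i],
      parent = tree$edge[, 1],
      child = tree$edge[, 2],
      child_label = ifelse(tree$edge[, 2] <= ntip,
                           tree$tip.label[tree$edge[, 2]],
                           paste0("node", tree$edge[, 2])),
      delta = map_state[tree$edge[, 2]] - map_state[tree$edge[, 1]],
      root_state = map_state[root])
  })

  avg <- deltas %>%
    dplyr::filter(.data$child_label %in% tree$tip.label) %>%
    dplyr::group_by(species = .data$child_label) %>%
    dplyr::summarise(average_expansion = mean(.data$delta), .groups = "drop")

  structure(list(
    branch_deltas = dplyr::select(deltas, -"root_state"),
    average_expansion = avg,
    root_states = dplyr::distinct(deltas, .data$family_id, .data$root_state),
    lambda = lambda),
    class = "nlr_bdp")
}

#' @export
print.nlr_bdp <- function(x, ...) {
  cat("<nlr_bdp> lambda ", x$lambda, ", ",
      dplyr::n_distinct(x$branch_deltas$family_id), " families\n", sep = "")
  print(x$average_expansion)
  invisible(x)
}

#' @rdname branch_changes
#' @param x,object An `nlr_bdp` object.
#' @param ... Unused.
#' @export
tidy.nlr_bdp <- function(x, ...) x$branch_deltas

#' @rdname branch_changes
#' @export
glance.nlr_bdp <- function(x, ...) {
  tidyr::pivot_wider(x$average_expansion, names_from = "species",
                     values_from = "average_expansion") %>%
    dplyr::mutate(lambda = x$lambda, .before = 1)
}

#' @rdname branch_changes
#' @export
autoplot.nlr_bdp <- function(object, ...) {
  ggplot2::ggplot(object$average_expansion,
                  ggplot2::aes(x = .data$species, y = .data$average_expansion,
                               fill = .data$average_expansion > 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::labs(x = NULL, y = "average expansion (genes per family)") +
    ggplot2::theme_minimal()
}

#' Monte-Carlo p-values for rapidly evolving families
#'
#' For each family, the root size is fixed at its maximum-posterior
#' state and `n_sim` profiles are simulated down the tree from that
#' root under the fitted birth-death kernel; the p-value is
#' `(k + 1) / (n_sim + 1)` where `k` counts simulations whose
#' log-likelihood is at or below the observed family's (so p always
#' lies in (0, 1]).
#'
#' @inheritParams branch_changes
#' @param n_sim Simulations per family (default 1000).
#' @param seed Seed for the simulations.
#' @return Tibble: `family_id`, `loglik`, `p_value`.
#' @export
rapid_families <- function(profiles, tree, lambda, n_sim = 1000, seed = 1,
                           max_count = 100) {
  species <- setdiff(names(profiles), "family_id")
  tree <- stats::reorder(tree, "cladewise")
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  set.seed(seed)

  bc <- branch_changes(profiles, tree, lambda, max_count)
  roots <- bc$root_states

  Tms <- lapply(seq_len(nrow(tree$edge)), function(e) {
    Tm <- bdp_transition_matrix(tree$edge.length[e], lambda, max_count)
    Tm / pmax(rowSums(Tm), 1e-300)  # renormalised for sampling
  })

  sim_tips <- function(root_state) {
    st <- integer(ntip + tree$Nnode)
    st[root] <- root_state
    for (e in seq_len(nrow(tree$edge))) {
      par <- tree$edge[e, 1]; kid <- tree$edge[e, 2]
      st[kid] <- sample.int(max_count + 1L, 1L, prob = Tms[[e]][st[par] + 1L, ]) - 1L
    }
    stats::setNames(st[seq_len(ntip)], tree$tip.label)
  }

  purrr::map_dfr(seq_len(nrow(profiles)), function(i) {
    counts <- profile_counts(profiles, i, species)
    obs <- family_loglik(counts, tree, lambda, max_count)
    r0 <- roots$root_state[roots$family_id == profiles$family_id[i]][1]
    if (r0 < 1) r0 <- 1L
    sims <- vapply(seq_len(n_sim), function(z) {
      tips <- sim_tips(r0)
      family_loglik(tips[species], tree, lambda, max_count)
    }, numeric(1))
    tibble::tibble(family_id = profiles$family_id[i], loglik = obs,
                   p_value = (sum(sims <= obs) + 1) / (n_sim + 1))
  })
}
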