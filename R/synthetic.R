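#' Planted prescription-module model
#'
#' Specifies a generative model for incidence data with known module
#' structure: each study first draws one prescription module (a disjoint
#' group of acupoints) with probability `mixing`, then includes every
#' acupoint of that module independently with probability `p_within` and
#' every other acupoint with probability `p_background`. With
#' `p_within >> p_background`, within-group co-usage exceeds between-group
#' co-usage in expectation, so module detection should recover the groups.
#'
#' @param m number of studies, `>= 1`.
#' @param groups named list of disjoint character vectors of acupoint labels.
#' @param p_within within-module inclusion probability.
#' @param p_background background inclusion probability,
#'   `0 <= p_background <= p_within <= 1`.
#' @param mixing module choice weights (recycled to uniform when `NULL`);
#'   normalized to sum to 1.
#' @param seed integer seed.
#' @return An object of class `"planted_model"`.
#' @export
planted_model <- function(m, groups, p_within = 0.9, p_background = 0.05,
                          mixing = NULL, seed = 1L) {
  if (length(groups) == 0L) stop("module_spec is empty: need at least one group")
  labels <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(labels)) stop("groups must be disjoint")
  if (!(p_background >= 0 && p_background <= p_within && p_within <= 1)) {
    stop("need 0 <= p_background <= p_within <= 1")
  }
  if (is.null(mixing)) mixing <- rep(1, length(groups))
  if (length(mixing) != length(groups) || any(mixing < 0) || sum(mixing) == 0) {
    stop("mixing must be non-negative weights, one per group")
  }
  structure(list(m = as.integer(m), groups = groups,
                 p_within = p_within, p_background = p_background,
                 mixing = mixing / sum(mixing), seed = as.integer(seed)),
            class = "planted_model")
}

with_local_seed <- function(seed, expr) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) {
    assign(".Random.seed", old_seed, envir = globalenv())
  } else if (exists(".Random.seed", envir = globalenv())) {
    rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Generate incidence data from a planted model
#'
#' @param model a [planted_model()].
#' @return A [prescription_dataset()]; bit-reproducible for a fixed seed.
#' @examples
#' mod <- planted_model(10, list(A = c("BL23", "BL24", "BL25"),
#'                               B = c("GB30", "GB34", "ST36")),
#'                      p_within = 1, p_background = 0, seed = 7)
#' generate_planted(mod)
#' @export
generate_planted <- function(model) {
  stopifnot(inherits(model, "planted_model"))
  labels <- unlist(model$groups, use.names = FALSE)
  p <- length(labels)
  group_of <- rep(seq_along(model$groups), lengths(model$groups))
  with_local_seed(model$seed, {
    chosen <- sample.int(length(model$groups), model$m, replace = TRUE,
                         prob = model$mixing)
    inc <- matrix(0L, model$m, p)
    for (i in seq_len(model$m)) {
      pr <- ifelse(group_of == chosen[i], model$p_within, model$p_background)
      inc[i, ] <- as.integer(stats::runif(p) < pr)
    }
    ds <- prescription_dataset(inc, acupoint_labels = labels)
    attr(ds, "planted") <- stats::setNames(group_of, labels)
    attr(ds, "seed") <- model$seed
    ds
  })
}

#' Fixture specification: marginal and pairwise usage constraints
#'
#' Describes an incidence dataset by its exact per-acupoint usage counts and,
#' for selected unordered acupoint pairs, exact co-usage counts. Feasibility
#' requires `max(0, n_x + n_y - m) <= n_xy <= min(n_x, n_y)` for every
#' constrained pair (the Frechet bounds).
#'
#' @param m total number of studies.
#' @param marginal_counts named integer vector, each in `[0, m]`.
#' @param pair_counts `NULL`, or a data frame with columns `a`, `b`, `count`.
#' @param seed integer seed controlling row placement among equivalent
#'   completions.
#' @return An object of class `"fixture_spec"`.
#' @export
fixture_spec <- function(m, marginal_counts, pair_counts = NULL, seed = 1L) {
  m <- as.integer(m)
  if (is.null(names(marginal_counts)) || anyDuplicated(names(marginal_counts))) {
    stop("marginal_counts must be uniquely named by acupoint")
  }
  if (any(marginal_counts < 0L) || any(marginal_counts > m)) {
    stop("marginal counts must lie in [0, m]")
  }
  if (!is.null(pair_counts)) {
    stopifnot(is.data.frame(pair_counts),
              all(c("a", "b", "count") %in% names(pair_counts)))
    pair_counts$count <- as.integer(pair_counts$count)
    for (i in seq_len(nrow(pair_counts))) {
      a <- pair_counts$a[i]; b <- pair_counts$b[i]; k <- pair_counts$count[i]
      if (!a %in% names(marginal_counts) || !b %in% names(marginal_counts)) {
        stop(sprintf("pair (%s, %s) references an unknown acupoint", a, b))
      }
      na <- marginal_counts[[a]]; nb <- marginal_counts[[b]]
      if (k < max(0L, na + nb - m) || k > min(na, nb)) {
        stop(sprintf("infeasible pair (%s, %s): co-usage %d outside [%d, %d]",
                     a, b, k, max(0L, na + nb - m), min(na, nb)))
      }
    }
  }
  structure(list(m = m,
                 marginal_counts = as.integer(marginal_counts) |>
                   stats::setNames(names(marginal_counts)),
                 pair_counts = pair_counts,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

# enumerate non-negative group allocations c (one per constraint-pattern
# group) with sum(c) = total, per-group capacity caps, and, for each
# constraint j, the allocations of groups whose pattern includes j summing
# to targets[j]; returns up to `limit` allocations, deterministic order
# (larger allocations to earlier groups first)
enumerate_allocations <- function(group_caps, group_patterns, targets, total,
                                  limit = 4096L) {
  n_grp <- length(group_caps)
  sols <- list()
  alloc <- integer(n_grp)
  # suffix sums for pruning: how much the groups >= i can still contribute
  # to each constraint / to the total
  n_con <- ncol(group_patterns)
  suffix_cap <- matrix(0L, n_grp + 1L, n_con)
  suffix_tot <- integer(n_grp + 1L)
  for (i in rev(seq_len(n_grp))) {
    suffix_tot[i] <- suffix_tot[i + 1L] + group_caps[i]
    suffix_cap[i, ] <- suffix_cap[i + 1L, ] +
      group_caps[i] * (group_patterns[i, ] > 0)
  }
  rec <- function(i, rem_total, rem_targets) {
    if (length(sols) >= limit) return(invisible())
    if (i > n_grp) {
      if (rem_total == 0L && all(rem_targets == 0L)) {
        sols[[length(sols) + 1L]] <<- alloc[]
      }
      return(invisible())
    }
    if (rem_total > suffix_tot[i]) return(invisible())
    if (any(rem_targets > suffix_cap[i, ])) return(invisible())
    in_con <- group_patterns[i, ] > 0
    hi <- min(group_caps[i], rem_total,
              if (any(in_con)) min(rem_targets[in_con]) else rem_total)
    if (hi < 0L) return(invisible())
    for (c in hi:0L) {
      alloc[i] <<- c
      rec(i + 1L, rem_total - c, rem_targets - c * in_con)
      if (length(sols) >= limit) break
    }
    alloc[i] <<- 0L
  }
  rec(1L, total, as.integer(targets))
  sols
}

#' Build an incidence dataset satisfying exact count constraints
#'
#' Deterministically searches for an m x p binary matrix whose column sums
#' equal the specified marginal counts and whose co-usage counts equal the
#' specified pair counts. Constrained acupoints are placed one at a time in
#' decreasing order of constraint degree; each placement allocates usages
#' across the membership cells induced by the already-placed acupoints of
#' its constraint component, with depth-first backtracking across
#' allocations. Rows within a cell are taken in a seed-shuffled but fixed
#' order, so the result is bit-reproducible. Unconstrained acupoints are
#' filled by seeded sampling.
#'
#' @param spec a [fixture_spec()].
#' @param max_alloc backtracking width per placement (group allocations
#'   retained per acupoint before the search gives up).
#' @return A [prescription_dataset()] that re-tallies exactly to `spec`.
#' @examples
#' sp <- fixture_spec(3, c(A = 2, B = 1),
#'                    data.frame(a = "A", b = "B", count = 1))
#' colSums(build_fixture(sp)$incidence)
#' @export
build_fixture <- function(spec, max_alloc = 4096L) {
  stopifnot(inherits(spec, "fixture_spec"))
  m <- spec$m
  labels <- names(spec$marginal_counts)
  pc <- spec$pair_counts
  inc <- matrix(0L, m, length(labels),
                dimnames = list(paste0("S", seq_len(m)), labels))

  if (!is.null(pc) && nrow(pc)) {
    # connected components of the constraint graph
    comp <- stats::setNames(seq_along(labels), labels)
    for (i in seq_len(nrow(pc))) {
      ca <- comp[[pc$a[i]]]; cb <- comp[[pc$b[i]]]
      if (ca != cb) comp[comp == cb] <- ca
    }
    constrained <- unique(c(pc$a, pc$b))
    # canonical component order: by smallest member label; each component
    # gets its own seeded row shuffle so that pairs in different components
    # overlap near independence rather than packing into the same rows
    cids <- unique(comp[constrained])
    firsts <- vapply(cids, function(cid) {
      min(intersect(labels[comp == cid], constrained))
    }, character(1))
    cids <- cids[order(firsts)]
    for (ci in seq_along(cids)) {
      members <- intersect(labels[comp == cids[ci]], constrained)
      ndeg <- vapply(members, function(x) sum(pc$a == x | pc$b == x), integer(1))
      members <- members[order(-ndeg, -spec$marginal_counts[members], members)]
      row_order <- with_local_seed(spec$seed + 101L * ci, sample.int(m))
      sets <- place_component(members, spec, pc, row_order, max_alloc)
      for (x in members) inc[sets[[x]], x] <- 1L
    }
  } else {
    constrained <- character(0)
  }

  free <- setdiff(labels, constrained)
  with_local_seed(spec$seed + 1L, {
    for (x in free) {
      n_x <- spec$marginal_counts[[x]]
      if (n_x > 0L) inc[sample.int(m, n_x), x] <- 1L
    }
  })

  ds <- prescription_dataset(inc)
  verify_fixture(ds, spec)
  ds
}

# DFS with backtracking over the acupoints of one constraint component.
# For each acupoint the rows are partitioned into membership cells over
# *all* previously placed members (so row identity within a cell cannot
# affect later constraints); cells are aggregated into groups by their
# pattern over the acupoint's constrained neighbours (<= 2^r groups), the
# group allocations satisfying the co-usage targets are enumerated
# completely, and each group's quota is spilled across its member cells in
# deterministic (seed-shuffled row, lexicographic cell) order. Backtracking
# runs over group allocations and, through recursion, over earlier
# placements.
place_component <- function(members, spec, pc, row_order, max_alloc,
                            budget = 200000L) {
  m <- spec$m
  sets <- list()
  tries <- 0L
  target_of <- function(x, y) {
    hit <- (pc$a == x & pc$b == y) | (pc$a == y & pc$b == x)
    if (any(hit)) pc$count[which(hit)[1L]] else NA_integer_
  }
  rec <- function(k) {
    if (k > length(members)) return(TRUE)
    tries <<- tries + 1L
    if (tries > budget) {
      stop("fixture search timed out; the constraint system may be too tight")
    }
    x <- members[k]
    placed <- members[seq_len(k - 1L)]
    nbrs <- placed[vapply(placed, function(y) !is.na(target_of(x, y)), logical(1))]
    # membership pattern of every row over the placed sets
    key <- if (length(placed)) {
      pat <- vapply(placed, function(y) as.integer(row_order %in% sets[[y]]),
                    integer(m))
      apply(pat, 1L, paste, collapse = "")
    } else {
      rep("", m)
    }
    cells <- split(row_order, key)
    sizes <- lengths(cells)
    # aggregate cells by their pattern over x's constrained neighbours
    con_idx <- match(nbrs, placed)
    cell_proj <- vapply(names(cells), function(kk) {
      bits <- as.integer(strsplit(kk, "")[[1L]])
      paste(bits[con_idx], collapse = "")
    }, character(1))
    groups <- split(seq_along(cells), cell_proj)
    group_patterns <- matrix(0L, length(groups), length(nbrs))
    if (length(nbrs)) {
      group_patterns[] <- t(vapply(names(groups), function(q) {
        as.integer(strsplit(q, "")[[1L]])
      }, integer(length(nbrs))))
    }
    group_caps <- vapply(groups, function(ci) sum(sizes[ci]), integer(1))
    targets <- vapply(nbrs, function(y) target_of(x, y), integer(1))
    galloc <- enumerate_allocations(group_caps, group_patterns, targets,
                                    spec$marginal_counts[[x]], limit = max_alloc)
    # for each group allocation, search the compositions of each group's
    # quota over its member cells; depth-first, deterministic order (take
    # from earlier cells first)
    cell_alloc <- integer(length(cells))
    comp_rec <- function(gi, ci_pos, need) {
      if (gi > length(groups)) {
        rows <- integer(0)
        for (ci in which(cell_alloc > 0L)) {
          rows <- c(rows, cells[[ci]][seq_len(cell_alloc[ci])])
        }
        sets[[x]] <<- rows
        return(rec(k + 1L))
      }
      cis <- groups[[gi]]
      if (ci_pos > length(cis)) {
        if (need == 0L) return(comp_rec(gi + 1L, 1L, NA_integer_))
        return(FALSE)
      }
      if (is.na(need)) need <- galloc_cur[gi]
      ci <- cis[ci_pos]
      rest_cap <- if (ci_pos < length(cis)) sum(sizes[cis[(ci_pos + 1L):length(cis)]]) else 0L
      hi <- min(sizes[ci], need)
      lo <- max(0L, need - rest_cap)
      if (hi < lo) return(FALSE)
      for (c in hi:lo) {
        cell_alloc[ci] <<- c
        if (comp_rec(gi, ci_pos + 1L, need - c)) return(TRUE)
      }
      cell_alloc[ci] <<- 0L
      FALSE
    }
    for (ga in galloc) {
      galloc_cur <- ga
      cell_alloc[] <- 0L
      if (comp_rec(1L, 1L, NA_integer_)) return(TRUE)
    }
    sets[[x]] <<- NULL
    FALSE
  }
  if (!rec(1L)) {
    stop(sprintf("fixture search failed: could not satisfy the pair constraints among {%s}",
                 paste(members, collapse = ", ")))
  }
  sets
}

# re-tally and assert every constraint of the spec
verify_fixture <- function(ds, spec) {
  cs <- colSums(ds$incidence)
  if (!all(cs[names(spec$marginal_counts)] == spec$marginal_counts)) {
    bad <- names(which(cs[names(spec$marginal_counts)] != spec$marginal_counts))[1L]
    stop(sprintf("fixture verification failed: marginal count of '%s' is %d, expected %d",
                 bad, cs[[bad]], spec$marginal_counts[[bad]]))
  }
  pc <- spec$pair_counts
  if (!is.null(pc)) {
    for (i in seq_len(nrow(pc))) {
      k <- sum(ds$incidence[, pc$a[i]] * ds$incidence[, pc$b[i]])
      if (k != pc$count[i]) {
        stop(sprintf("fixture verification failed: co-usage of (%s, %s) is %d, expected %d",
                     pc$a[i], pc$b[i], k, pc$count[i]))
      }
    }
  }
  invisible(TRUE)
}

#' Infer an integer co-usage count from a rounded MI value
#'
#' Enumerates every feasible co-usage count `k` in
#' `[max(0, n_x + n_y - m), min(n_x, n_y)]` and returns the one whose
#' [pair_mi()] value rounds (half-up) to `mi` at `digits` decimals. Used to
#' reconstruct pair counts from published MI tables; errors unless the match
#' is unique.
#'
#' @param n_x,n_y marginal counts.
#' @param m number of studies.
#' @param mi published MI value, rounded to `digits` decimals.
#' @param digits decimals of the published value (default 4).
#' @return The unique matching integer count.
#' @export
infer_pair_count <- function(n_x, n_y, m, mi, digits = 4L) {
  ks <- max(0L, n_x + n_y - m):min(n_x, n_y)
  vals <- vapply(ks, function(k) pair_mi(n_x, n_y, k, m), numeric(1))
  hit <- ks[round_half_up(vals, digits) == mi]
  if (length(hit) == 0L) {
    stop(sprintf("no co-usage count reproduces MI = %.4f for marginals (%d, %d), m = %d",
                 mi, n_x, n_y, m))
  }
  if (length(hit) > 1L) {
    stop(sprintf("MI = %.4f is ambiguous for marginals (%d, %d): counts %s all match",
                 mi, n_x, n_y, paste(hit, collapse = ", ")))
  }
  hit
}
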