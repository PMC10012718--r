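# Presence/absence analytics: building the intron x clade matrix, Euler
# region counts, and asymmetric-cost (gain vs loss) Sankoff parsimony over
# alternative rooted land-plant phylogenies.

#' Preset clade topologies
#'
#' Two rooted cladograms over the seven embryophyte clades plus the algal
#' outgroup:
#' * `NLE_HT`: liverworts sister to all other embryophytes
#'   (Non-Liverwort-Embryophyte clade) and hornworts sister to tracheophytes
#'   (Hornwort-Tracheophyte clade).
#' * `BRY_SET`: monophyletic bryophytes with a moss + liverwort (Setaphyte)
#'   clade, sister to the tracheophytes.
#'
#' @param name `"NLE_HT"` or `"BRY_SET"`.
#' @return an `ape` `phylo` object (tips use the canonical `SAL` code for
#'   the algae).
#' @export
preset_topology <- function(name = c("NLE_HT", "BRY_SET")) {
  name <- match.arg(name)
  nwk <- system.file("extdata", "topologies",
                     if (name == "NLE_HT") "nle_ht.nwk" else "bry_set.nwk",
                     package = "intronfam")
  read_newick(nwk)
}

#' Build the binary presence/absence matrix from intron records
#'
#' A cell is 1 iff at least one non-fossil, non-pseudogene-context record of
#' that insertion site occurs in that clade; fossil and pseudogene-context
#' records are excluded (and reported via the `excluded` attribute).
#'
#' @param records an [intron_records()] table.
#' @param clades column order (defaults to the eight canonical codes).
#' @return integer matrix, attribute `excluded` listing skipped records.
#' @export
build_matrix <- function(records, clades = CLADE_CODES) {
  skip <- records$splicing_status == "fossil" |
    grepl("pseudogene", records$splicing_status)
  used <- records[!skip, , drop = FALSE]
  sites <- sort(unique(used$site))
  m <- matrix(0L, nrow = length(sites), ncol = length(clades),
              dimnames = list(sites, clades))
  for (i in seq_len(nrow(used)))
    m[used$site[i], used$clade[i]] <- 1L
  attr(m, "excluded") <- paste(records$label[skip], records$taxon[skip],
                               sep = ".")
  m
}

#' Euler region counts for unions of clade columns
#'
#' Counts, for up to four sets defined as unions of matrix columns, the
#' number of introns in every non-empty intersection region (2^k - 1
#' regions, exact enumeration).
#'
#' @param matrix presence/absence matrix.
#' @param sets named list; each element is a character vector of clade
#'   columns whose union defines the set.
#' @return data.frame: `region` (e.g. `"A&B"`), one indicator column per
#'   set, and `count`.
#' @export
euler_counts <- function(matrix, sets) {
  k <- length(sets)
  if (k > 4) stop("at most 4 sets are supported", call. = FALSE)
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("sets must be named", call. = FALSE)
  member <- sapply(sets, function(cols) {
    cols <- normalize_clade(cols)
    rowSums(matrix[, cols, drop = FALSE]) > 0
  })
  member <- matrix(member, ncol = k, dimnames = list(rownames(matrix), names(sets)))
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), k))
  names(combos) <- names(sets)
  combos <- combos[rowSums(combos) > 0, , drop = FALSE]
  counts <- apply(combos, 1, function(cmb) {
    sum(apply(member, 1, function(r) all(r == as.logical(cmb))))
  })
  region <- apply(combos, 1, function(cmb)
    paste(names(sets)[as.logical(cmb)], collapse = "&"))
  out <- data.frame(region = region, combos, count = as.integer(counts),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Intersection size of two column-union sets
#'
#' @param matrix presence/absence matrix.
#' @param a,b character vectors of clade columns.
#' @return number of introns present in both unions.
#' @export
set_intersection_size <- function(matrix, a, b) {
  ina <- rowSums(matrix[, normalize_clade(a), drop = FALSE]) > 0
  inb <- rowSums(matrix[, normalize_clade(b), drop = FALSE]) > 0
  sum(ina & inb)
}

# postorder edge list and children map for a rooted phylo
tree_tables <- function(phy) {
  phy <- ape::reorder.phylo(phy, "postorder")
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  children <- vector("list", nnode)
  for (e in seq_len(nrow(phy$edge))) {
    p <- phy$edge[e, 1]; c <- phy$edge[e, 2]
    children[[p]] <- c(children[[p]], c)
  }
  root <- ntip + 1L
  list(phy = phy, ntip = ntip, nnode = nnode, children = children, root = root)
}

# node label for reporting: tip name or internal code node<k>
node_name <- function(tt, v) {
  if (v <= tt$ntip) tt$phy$tip.label[v] else paste0("node", v - tt$ntip)
}

#' Weighted gain-loss parsimony (Sankoff) for one or many introns
#'
#' Minimum-cost binary ancestral reconstruction with per-branch transition
#' costs `cost(0->1) = w_gain` and `cost(1->0) = w_loss`. The root prior
#' charges `w_gain` for presence at the root (a root-stem gain), so every
#' presence is ultimately explained by at least one gain. Co-optimal
#' labelings are resolved by the tie policy; the default `min-gains`
#' minimizes the number of gains among minimum-cost labelings, then losses,
#' then prefers absence - implemented exactly by a lexicographic
#' (cost, gains, losses, presences) dynamic program.
#'
#' @param matrix presence/absence matrix (columns must match the tree's
#'   tips).
#' @param topology rooted `phylo` tree.
#' @param w_gain,w_loss positive transition weights (default 4:1 for gains
#'   over losses).
#' @param tie_policy `"min-gains"` or `"max-gains"` (the latter prefers
#'   gains among co-optima, for co-optimum reporting).
#' @param root_prior `"gain"` (presence at root costs `w_gain`) or
#'   `"free"`.
#' @return list with `totals` (gains, losses, weighted cost, steps),
#'   `per_intron` data.frame, `events` data.frame (intron, branch, event)
#'   and the policy metadata.
#' @export
sankoff_gainloss <- function(matrix, topology, w_gain = 4, w_loss = 1,
                             tie_policy = c("min-gains", "max-gains"),
                             root_prior = c("gain", "free")) {
  tie_policy <- match.arg(tie_policy)
  root_prior <- match.arg(root_prior)
  if (w_gain <= 0 || w_loss <= 0) stop("weights must be positive", call. = FALSE)
  tips <- topology$tip.label
  if (!all(tips %in% colnames(matrix)))
    stop("matrix lacks columns for leaves: ",
         paste(setdiff(tips, colnames(matrix)), collapse = ", "), call. = FALSE)
  tt <- tree_tables(topology)
  gain_sign <- if (tie_policy == "min-gains") 1 else -1
  events <- list(); per <- list()
  for (ri in seq_len(nrow(matrix))) {
    states <- as.integer(matrix[ri, tips])
    r <- sankoff_one(tt, states, w_gain, w_loss, gain_sign, root_prior)
    per[[ri]] <- data.frame(intron = rownames(matrix)[ri],
                            gains = r$gains, losses = r$losses,
                            cost = r$cost, stringsAsFactors = FALSE)
    if (nrow(r$events) > 0) {
      r$events$intron <- rownames(matrix)[ri]
      events[[length(events) + 1L]] <- r$events
    }
  }
  per <- do.call(rbind, per)
  ev <- if (length(events) > 0) do.call(rbind, events)[, c("intron", "branch", "event")]
        else data.frame(intron = character(0), branch = character(0),
                        event = character(0))
  totals <- list(gains = sum(per$gains), losses = sum(per$losses),
                 cost = w_gain * sum(per$gains) + w_loss * sum(per$losses),
                 steps = sum(per$gains) + sum(per$losses))
  list(totals = totals, per_intron = per, events = ev,
       weights = c(gain = w_gain, loss = w_loss), tie_policy = tie_policy,
       root_prior = root_prior)
}

# Lexicographic Sankoff DP for one binary character.
# Objective per labeling: (weighted cost, gain_sign * gains, losses,
# presences); componentwise-additive tuples compared lexicographically.
sankoff_one <- function(tt, tip_states, w_gain, w_loss, gain_sign, root_prior) {
  nn <- tt$nnode; ntip <- tt$ntip
  # tuple per node per state: cost, g, l, p (presences, used as final tiebreak)
  C <- array(Inf, dim = c(nn, 2, 4))
  # children choices stored per node in a list
  pick <- vector("list", nn)
  lt <- function(a, b) {
    for (k in 1:4) {
      if (a[k] < b[k] - 1e-9) return(TRUE)
      if (a[k] > b[k] + 1e-9) return(FALSE)
    }
    FALSE
  }
  trans_tuple <- function(from, to) {
    if (from == 0 && to == 1) c(w_gain, gain_sign * 1, 0, 0)
    else if (from == 1 && to == 0) c(w_loss, 0, 1, 0)
    else c(0, 0, 0, 0)
  }
  for (v in seq_len(ntip)) {
    s <- tip_states[v]
    C[v, s + 1, ] <- c(0, 0, 0, s)
    C[v, 2 - s, ] <- c(Inf, Inf, Inf, Inf)
  }
  ord <- unique(tt$phy$edge[, 1])  # postorder parents
  for (p in ord) {
    kids <- tt$children[[p]]
    pick[[p]] <- matrix(NA_integer_, nrow = 2, ncol = length(kids))
    for (s in 0:1) {
      tot <- c(0, 0, 0, s)
      ok <- TRUE
      for (ki in seq_along(kids)) {
        k <- kids[ki]
        best <- NULL; bstate <- NA_integer_
        for (cs in 0:1) {
          if (!is.finite(C[k, cs + 1, 1])) next
          cand <- C[k, cs + 1, ] + trans_tuple(s, cs)
          # prefer child state 0 on exact ties
          if (is.null(best) || lt(cand, best) ||
              (!lt(best, cand) && !lt(cand, best) && cs == 0 && bstate == 1)) {
            best <- cand; bstate <- cs
          }
        }
        if (is.null(best)) { ok <- FALSE; break }
        tot <- tot + best
        pick[[p]][s + 1, ki] <- bstate
      }
      C[p, s + 1, ] <- if (ok) tot else c(Inf, Inf, Inf, Inf)
    }
  }
  root <- tt$root
  r0 <- C[root, 1, ]
  r1 <- C[root, 2, ]
  if (root_prior == "gain") r1 <- r1 + c(w_gain, gain_sign * 1, 0, 0)
  root_state <- if (lt(r1, r0)) 1L else 0L  # ties prefer absence
  final <- if (root_state == 1L) r1 else r0
  # backtrace
  state <- integer(nn)
  state[root] <- root_state
  evs <- list()
  if (root_state == 1L && root_prior == "gain")
    evs[[length(evs) + 1L]] <- data.frame(branch = "root", event = "gain",
                                          stringsAsFactors = FALSE)
  # preorder traversal
  stack <- root
  while (length(stack) > 0) {
    p <- stack[length(stack)]; stack <- stack[-length(stack)]
    kids <- tt$children[[p]]
    if (is.null(kids)) next
    for (ki in seq_along(kids)) {
      k <- kids[ki]
      cs <- pick[[p]][state[p] + 1, ki]
      state[k] <- cs
      if (cs != state[p]) {
        evs[[length(evs) + 1L]] <- data.frame(
          branch = node_name(tt, k),
          event = if (cs == 1) "gain" else "loss", stringsAsFactors = FALSE)
      }
      stack <- c(stack, k)
    }
  }
  ev <- if (length(evs) > 0) do.call(rbind, evs)
        else data.frame(branch = character(0), event = character(0))
  gains <- sum(ev$event == "gain")
  losses <- sum(ev$event == "loss")
  list(cost = w_gain * gains + w_loss * losses, gains = gains,
       losses = losses, events = ev, node_states = state)
}

#' Compare gain-loss totals between two topologies
#'
#' Runs [sankoff_gainloss()] on both topologies with the same matrix and
#' weights and reports gains, losses, weighted cost, unweighted step count
#' and their differences (A minus B).
#'
#' @param matrix presence/absence matrix.
#' @param topoA,topoB rooted `phylo` topologies.
#' @param w_gain,w_loss weights.
#' @param ... passed to [sankoff_gainloss()].
#' @return data.frame with one row per topology plus a `difference` row.
#' @export
compare_topologies <- function(matrix, topoA, topoB, w_gain = 4, w_loss = 1,
                               ...) {
  a <- sankoff_gainloss(matrix, topoA, w_gain, w_loss, ...)
  b <- sankoff_gainloss(matrix, topoB, w_gain, w_loss, ...)
  df <- data.frame(topology = c("A", "B", "A-B"),
                   gains = c(a$totals$gains, b$totals$gains,
                             a$totals$gains - b$totals$gains),
                   losses = c(a$totals$losses, b$totals$losses,
                              a$totals$losses - b$totals$losses),
                   cost = c(a$totals$cost, b$totals$cost,
                            a$totals$cost - b$totals$cost),
                   steps = c(a$totals$steps, b$totals$steps,
                             a$totals$steps - b$totals$steps))
  attr(df, "runs") <- list(A = a, B = b)
  df
}

#' Empirical gain-weight selection
#'
#' For each candidate gain:loss weighting, computes the total number of gain
#' events and chooses the weighting whose gain total is smallest while still
#' at least `target_gains` (one origin per distinct intron); ties prefer the
#' smaller gain total, then the larger gain weight. When all candidates give
#' exactly `target_gains` the choice is flagged indifferent.
#'
#' @param matrix presence/absence matrix.
#' @param topology rooted topology.
#' @param candidates list of `c(w_gain, w_loss)` pairs.
#' @param target_gains minimum conceivable number of gains (defaults to the
#'   number of introns).
#' @return list with `chosen` (`c(w_gain, w_loss)`), `indifferent`, and the
#'   full `table`.
#' @export
select_weight <- function(matrix, topology,
                          candidates = list(c(8, 1), c(4, 1), c(2, 1), c(1, 1)),
                          target_gains = nrow(matrix)) {
  tab <- do.call(rbind, lapply(candidates, function(w) {
    r <- sankoff_gainloss(matrix, topology, w[1], w[2])
    data.frame(w_gain = w[1], w_loss = w[2], gains = r$totals$gains,
               losses = r$totals$losses, cost = r$totals$cost)
  }))
  elig <- tab[tab$gains >= target_gains, , drop = FALSE]
  pool <- if (nrow(elig) > 0) elig else tab
  pool <- pool[order(pool$gains, -pool$w_gain), , drop = FALSE]
  chosen <- pool[1, ]
  list(chosen = c(w_gain = chosen$w_gain, w_loss = chosen$w_loss),
       indifferent = length(unique(tab$gains)) == 1L &&
         all(tab$gains == target_gains),
       table = tab)
}
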