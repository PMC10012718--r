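# Most-distant-ortholog (MDO) clustering of insertion sites into families of
# related paralogues, with the refinement rules (positional rescue,
# low-score gating) and maturase-driven superfamily assembly.

#' All-vs-all similarity scan of an intron record collection
#'
#' Runs the sensitive seeded search for every unordered pair of records
#' (self-comparisons excluded); symmetric pairs are deduplicated keeping the
#' orientation with the higher bit score. Low-complexity tracts are masked
#' before seeding.
#'
#' @param records an [intron_records()] table (needs unique record ids; the
#'   row name `label.taxon` is used).
#' @param scheme a [scoring_scheme()].
#' @param evalue_max expectation cutoff for reported hits.
#' @param mask mask low-complexity tracts before seeding.
#' @return hit table as from [seeded_local_search()] plus `query_site`,
#'   `subject_site`, `query_taxon`, `subject_taxon`.
#' @export
all_vs_all <- function(records, scheme = scoring_scheme(), evalue_max = 1e-5,
                       mask = TRUE) {
  n <- nrow(records)
  if (n < 2L) {
    warning("fewer than two records; empty hit table")
    h <- empty_hits()
    h$query_site <- character(0); h$subject_site <- character(0)
    h$query_taxon <- character(0); h$subject_taxon <- character(0)
    return(h)
  }
  ids <- paste(records$label, records$taxon, sep = ".")
  seqs <- records$sequence
  if (mask) seqs <- vapply(seqs, mask_low_complexity, character(1), USE.NAMES = FALSE)
  # canonical record order for determinism
  ord <- order(ids)
  out <- list()
  for (a in seq_len(n - 1L)) for (b in (a + 1L):n) {
    i <- ord[a]; j <- ord[b]
    h1 <- seeded_local_search(seqs[i], seqs[j], scheme,
                              evalue_max = evalue_max,
                              query_id = ids[i], subject_id = ids[j])
    if (nrow(h1) == 0L) next
    h1 <- h1[1, , drop = FALSE]  # best strand
    h1$query_site <- records$site[i]; h1$subject_site <- records$site[j]
    h1$query_taxon <- records$taxon[i]; h1$subject_taxon <- records$taxon[j]
    out[[length(out) + 1L]] <- h1
  }
  if (length(out) == 0L) {
    h <- empty_hits()
    h$query_site <- character(0); h$subject_site <- character(0)
    h$query_taxon <- character(0); h$subject_taxon <- character(0)
    return(h)
  }
  res <- do.call(rbind, out)
  res <- res[order(-res$bits, res$query, res$subject), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Per-site most-distant-ortholog cutoffs
#'
#' For every insertion site with at least two members, the MDO cutoff is the
#' minimum bit score over all same-site cross-taxon (orthologue) pairs that
#' produced a significant hit. Orthologue pairs with no significant hit are
#' counted (`n_missing`) but do not zero the cutoff - such "unbridged"
#' distances are handled by positional rescue, not by opening the family
#' gate. Single-member sites receive an infinite sentinel cutoff: they can
#' only be pulled into a family through another site's cutoff or maturase
#' evidence.
#'
#' @param hits hit table from [all_vs_all()].
#' @param records the record table that produced `hits`.
#' @return data.frame: `site`, `mdo_bitscore`, `n_ortholog_pairs`,
#'   `n_missing`, `n_members`.
#' @export
compute_mdo_cutoffs <- function(hits, records) {
  if (is.null(records$site)) stop("records lack site assignment", call. = FALSE)
  sites <- sort(unique(records$site))
  res <- lapply(sites, function(sk) {
    mem <- records[records$site == sk, , drop = FALSE]
    nm <- nrow(mem)
    if (nm < 2L)
      return(data.frame(site = sk, mdo_bitscore = Inf, n_ortholog_pairs = 0L,
                        n_missing = 0L, n_members = nm))
    sh <- hits[hits$query_site == sk & hits$subject_site == sk &
               hits$query_taxon != hits$subject_taxon, , drop = FALSE]
    npairs_total <- choose(nm, 2)
    if (nrow(sh) == 0L)
      return(data.frame(site = sk, mdo_bitscore = Inf,
                        n_ortholog_pairs = 0L, n_missing = npairs_total,
                        n_members = nm))
    data.frame(site = sk, mdo_bitscore = min(sh$bits),
               n_ortholog_pairs = nrow(sh),
               n_missing = npairs_total - nrow(sh), n_members = nm)
  })
  do.call(rbind, res)
}

#' Build the site graph under the MDO criterion
#'
#' Nodes are insertion sites. A cross-site hit creates an edge when its bit
#' score exceeds the MDO cutoff of at least one of the two sites (the
#' permissive one-sided rule; `two_sided = TRUE` requires both) and its
#' E-value is at most `evalue_max`. Edge weight is the best qualifying bit
#' score; the hit supplying it is recorded for the gating step.
#'
#' @param hits hit table from [all_vs_all()].
#' @param cutoffs from [compute_mdo_cutoffs()].
#' @param evalue_max significance gate.
#' @param two_sided require the hit to exceed both sites' cutoffs.
#' @return an igraph with vertex attribute `name` (site) and edge attributes
#'   `bits`, `n_hsps`, `qcov`, `rule`.
#' @export
build_family_graph <- function(hits, cutoffs, evalue_max = 1e-5,
                               two_sided = FALSE) {
  g <- igraph::make_empty_graph(directed = FALSE)
  g <- igraph::add_vertices(g, length(cutoffs$site), name = cutoffs$site)
  ch <- hits[hits$query_site != hits$subject_site &
             hits$evalue <= evalue_max, , drop = FALSE]
  if (nrow(ch) == 0L) return(g)
  cut <- stats::setNames(cutoffs$mdo_bitscore, cutoffs$site)
  pass <- if (two_sided) {
    ch$bits > cut[ch$query_site] & ch$bits > cut[ch$subject_site]
  } else {
    ch$bits > cut[ch$query_site] | ch$bits > cut[ch$subject_site]
  }
  ch <- ch[pass & !is.na(pass), , drop = FALSE]
  if (nrow(ch) == 0L) return(g)
  key <- ifelse(ch$query_site < ch$subject_site,
                paste(ch$query_site, ch$subject_site, sep = "\r"),
                paste(ch$subject_site, ch$query_site, sep = "\r"))
  best <- tapply(seq_len(nrow(ch)), key, function(idx) idx[which.max(ch$bits[idx])])
  ch <- ch[unlist(best), , drop = FALSE]
  for (i in seq_len(nrow(ch))) {
    g <- igraph::add_edges(g, c(ch$query_site[i], ch$subject_site[i]),
                           bits = ch$bits[i], n_hsps = ch$n_hsps[i],
                           qcov = ch$qcov[i], rule = "mdo")
  }
  g
}

#' Gate low-bit-score edges
#'
#' Edges supported only by a bit score below `bit_threshold` are retained
#' only when the supporting hit shows independent similarity in multiple
#' intron regions (at least `min_regions` non-overlapping HSPs) or covers at
#' least `min_coverage` of the query. Everything else is dropped and logged
#' as gated. This is the codified counterpart of re-inspecting taxonomically
#' isolated low-score links.
#'
#' @param graph from [build_family_graph()].
#' @param bit_threshold bit score below which gating applies.
#' @param min_regions minimum non-overlapping HSP regions.
#' @param min_coverage minimum query coverage.
#' @return the gated graph, with attribute `gated_edges` listing dropped
#'   pairs.
#' @export
gate_low_score_edges <- function(graph, bit_threshold = 200, min_regions = 2,
                                 min_coverage = 0.3) {
  if (igraph::ecount(graph) == 0L) {
    attr(graph, "gated_edges") <- character(0)
    return(graph)
  }
  bits <- igraph::E(graph)$bits
  n_hsps <- igraph::E(graph)$n_hsps
  qcov <- igraph::E(graph)$qcov
  low <- bits < bit_threshold
  keep_low <- n_hsps >= min_regions | qcov >= min_coverage
  drop <- which(low & !keep_low)
  ends <- igraph::as_edgelist(graph)
  gated <- apply(ends[drop, , drop = FALSE], 1, paste, collapse = "--")
  g2 <- igraph::delete_edges(graph, drop)
  attr(g2, "gated_edges") <- unname(gated)
  g2
}

#' Cluster sites into families (single linkage)
#'
#' Families are the connected components of the gated site graph with at
#' least two sites; remaining sites are solitary (`"S"`). Components are
#' numbered `F01`, `F02`, ... by descending size, ties by the
#' lexicographically smallest member label, so the output is independent of
#' input order.
#'
#' @param graph gated site graph.
#' @param prefix id prefix for families.
#' @return data.frame: `site`, `family`, `family_size`, `rule`.
#' @export
cluster_families <- function(graph, prefix = "F") {
  comp <- igraph::components(graph)
  sites <- igraph::V(graph)$name
  groups <- split(sites, comp$membership)
  groups <- lapply(groups, sort)
  fam <- groups[vapply(groups, length, integer(1)) >= 2L]
  if (length(fam) > 0) {
    ord <- order(-vapply(fam, length, integer(1)),
                 vapply(fam, `[`, "", 1))
    fam <- fam[ord]
    ids <- sprintf("%s%02d", prefix, seq_along(fam))
  } else ids <- character(0)
  rows <- list()
  for (k in seq_along(fam))
    rows[[length(rows) + 1L]] <- data.frame(site = fam[[k]], family = ids[k],
                                            family_size = length(fam[[k]]),
                                            rule = "mdo",
                                            stringsAsFactors = FALSE)
  solo <- setdiff(sites, unlist(fam))
  if (length(solo) > 0)
    rows[[length(rows) + 1L]] <- data.frame(site = sort(solo), family = "S",
                                            family_size = 1L, rule = "none",
                                            stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$family, out$site), , drop = FALSE]
}

#' Positional-orthologue refinement
#'
#' Records occupying a family's insertion site but lacking any significant
#' hit to that family are retained as positional orthologues (rescued). A
#' record whose best family-level similarity points at a *different* family
#' is flagged as a conflicting positional homologue rather than silently
#' moved.
#'
#' @param assignments from [cluster_families()].
#' @param records record table.
#' @param hits record-level hit table from [all_vs_all()].
#' @return data.frame per record: `label`, `taxon`, `site`, `family`,
#'   `rule` (`mdo`, `positional_rescue` or `conflicting_positional`),
#'   `best_other_family`, `best_other_bits`.
#' @export
refine_positional_orthologs <- function(assignments, records, hits) {
  fam_of <- stats::setNames(assignments$family, assignments$site)
  ids <- paste(records$label, records$taxon, sep = ".")
  res <- lapply(seq_len(nrow(records)), function(i) {
    own_fam <- fam_of[[records$site[i]]]
    mine <- hits[hits$query == ids[i] | hits$subject == ids[i], , drop = FALSE]
    if (nrow(mine) > 0) {
      other_site <- ifelse(mine$query == ids[i], mine$subject_site, mine$query_site)
      other_fam <- fam_of[other_site]
      per_fam <- tapply(mine$bits, other_fam, max)
    } else per_fam <- numeric(0)
    own_bits <- if (own_fam %in% names(per_fam)) per_fam[[own_fam]] else 0
    other <- per_fam[setdiff(names(per_fam), c(own_fam, "S"))]
    best_other <- if (length(other) > 0) names(other)[which.max(other)] else NA_character_
    best_other_bits <- if (length(other) > 0) max(other) else 0
    rule <- if (own_fam == "S") "none"
      else if (own_bits > 0 && own_bits >= best_other_bits) "mdo"
      else if (best_other_bits > own_bits && !is.na(best_other)) "conflicting_positional"
      else "positional_rescue"
    data.frame(label = records$label[i], taxon = records$taxon[i],
               site = records$site[i], family = own_fam, rule = rule,
               best_other_family = if (is.na(best_other)) "" else best_other,
               best_other_bits = best_other_bits, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Assemble superfamilies and maturase-based families
#'
#' Protein-level maturase clusters extend the nucleotide families: a cluster
#' spanning two or more core families unites them into a superfamily (id
#' `SF` plus the member family numbers, ascending); solitary sites falling in
#' a cluster with exactly one family join that family with rule
#' `maturase_link`; clusters made solely of solitary sites become
#' maturase-based families `mF` numbered after the last core family.
#'
#' @param assignments from [cluster_families()].
#' @param maturase_clusters data.frame with columns `site`, `cluster`.
#' @return assignments with updated `family`/`rule` plus a `superfamily`
#'   column (empty when none).
#' @export
assemble_superfamilies <- function(assignments, maturase_clusters) {
  out <- assignments
  out$superfamily <- ""
  if (is.null(maturase_clusters) || nrow(maturase_clusters) == 0L) return(out)
  ncore <- length(setdiff(unique(out$family), "S"))
  next_id <- ncore
  for (cl in sort(unique(maturase_clusters$cluster))) {
    sites <- sort(maturase_clusters$site[maturase_clusters$cluster == cl])
    sites <- intersect(sites, out$site)
    if (length(sites) < 2L) next
    fams <- unique(out$family[match(sites, out$site)])
    core <- sort(setdiff(fams, "S"))
    if (length(core) >= 2L) {
      nums <- sub("^[A-Za-z]+", "", core)
      sf <- paste0("SF", paste(nums, collapse = "-"))
      sel <- out$family %in% core | (out$site %in% sites & out$family == "S")
      out$superfamily[sel] <- sf
      link <- out$site %in% sites & out$family == "S"
      out$rule[link] <- "maturase_link"
    } else if (length(core) == 1L) {
      link <- out$site %in% sites & out$family == "S"
      if (!any(link)) next
      out$family[link] <- core
      out$rule[link] <- "maturase_link"
      out$family_size[out$family == core] <- sum(out$family == core)
    } else {
      next_id <- next_id + 1L
      mf <- sprintf("mF%02d", next_id)
      sel <- out$site %in% sites
      out$family[sel] <- mf
      out$family_size[sel] <- length(sites)
      out$rule[sel] <- "maturase_link"
    }
  }
  out[order(out$family, out$site), , drop = FALSE]
}

#' Run the complete family-classification pipeline on a record table
#'
#' Convenience wrapper: all-vs-all scan, MDO cutoffs, graph, gating, single
#' linkage clustering, positional refinement.
#'
#' @param records an [intron_records()] table.
#' @param scheme a [scoring_scheme()].
#' @param evalue_max expectation cutoff.
#' @param bit_threshold,min_regions,min_coverage gating parameters, see
#'   [gate_low_score_edges()].
#' @param two_sided MDO edge rule, see [build_family_graph()].
#' @return list with `hits`, `cutoffs`, `graph`, `site_families`,
#'   `record_families`.
#' @export
classify_families <- function(records, scheme = scoring_scheme(),
                              evalue_max = 1e-5, bit_threshold = 200,
                              min_regions = 2, min_coverage = 0.3,
                              two_sided = FALSE) {
  hits <- all_vs_all(records, scheme, evalue_max)
  cutoffs <- compute_mdo_cutoffs(hits, records)
  graph <- build_family_graph(hits, cutoffs, evalue_max, two_sided)
  graph <- gate_low_score_edges(graph, bit_threshold, min_regions, min_coverage)
  site_fam <- cluster_families(graph)
  rec_fam <- refine_positional_orthologs(site_fam, records, hits)
  list(hits = hits, cutoffs = cutoffs, graph = graph,
       site_families = site_fam, record_families = rec_fam)
}
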