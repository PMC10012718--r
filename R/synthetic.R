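# Simulator of plant-mitochondrial-style genome evolution with known truth:
# founder group II introns retrotranspose into new exon junctions, are lost
# along branches (optionally leaving degenerate fossil copies in spacers),
# accumulate substitutions under JC69/K2P, and carry maturase ORFs that decay
# by frameshift, premature stop or truncation. Every stochastic outcome is
# recorded so that tip genomes can be replayed from the event log.

GENE_POOL <- c("nad1", "cox1", "atp9", "cob", "nad5", "rps3", "cox2", "nad4",
               "atp1", "nad7", "ccmFC", "rpl2")

# default maturase domain layout used by the simulator (fractions of the
# protein length at which the packaged motif peptides are embedded)
SIM_MOTIF_AT <- c(RT = 0.35, X = 0.60, En = 0.85)

random_seq <- function(n) paste(sample(c("A", "C", "G", "U"), n, TRUE),
                                collapse = "")

# synonymous codon table (RNA) for reverse-translating simulator proteins;
# codons are sampled uniformly among synonyms so that frame-shifted readings
# behave like random sequence (realistic stop density off-frame)
CODON_SYNONYMS <- local({
  gc <- Biostrings::GENETIC_CODE
  syn <- split(chartr("T", "U", names(gc)), unname(gc))
  syn[names(syn) != "*"]
})
AA_LETTERS <- names(CODON_SYNONYMS)

revtrans <- function(protein) {
  aas <- strsplit(protein, "")[[1]]
  paste(vapply(CODON_SYNONYMS[aas], function(cs)
    if (length(cs) == 1L) cs else sample(cs, 1), character(1)), collapse = "")
}

#' Simulation parameters
#'
#' Bundles and validates the simulator's knobs. Defaults emulate the study
#' system at test scale: a handful of mitochondrial-style genes, founder
#' introns seeding distinct paralogue families, moderate retrotransposition
#' and loss, and decaying intron-borne maturases (see the methods vignette
#' for the rationale behind each default).
#'
#' @param tree `phylo` tree with branch lengths in substitutions/site, or a
#'   Newick string.
#' @param n_genes number of protein-coding genes.
#' @param exons_per_gene exons per gene (junctions = exons - 1 insertion
#'   sites per gene).
#' @param exon_len exon length (codons are padded to a multiple of 3).
#' @param spacer_len intergenic spacer length.
#' @param n_founder_introns founder introns (true families).
#' @param intron_core_len random core length between the 5' motif and
#'   domain V.
#' @param retro_rate per-intron per-branch retrotransposition probability.
#' @param loss_prob per-intron per-branch loss probability.
#' @param fossil_prob probability that a loss leaves a fossil copy in a
#'   random spacer.
#' @param fossil_extra_divergence extra divergence multiplier applied to
#'   fossil copies (relative to the branch length).
#' @param subst_model `"JC69"` or `"K2P"`.
#' @param kappa transition/transversion rate ratio for K2P.
#' @param maturase_frac fraction of founders carrying a maturase ORF.
#' @param maturase_aa maturase protein length (aa).
#' @param maturase_decay per-branch probability of a decay event on an
#'   intron's maturase.
#' @param decay_events decay event types to sample from; `"truncation"`
#'   physically deletes the ORF tail (structurally shortening the copy),
#'   the other two leave length intact.
#' @param seed mandatory integer seed.
#' @return validated parameter list of class `sim_params`.
#' @export
simulation_params <- function(tree, n_genes = 10, exons_per_gene = 8,
                              exon_len = 240, spacer_len = 300,
                              n_founder_introns = 5, intron_core_len = 350,
                              retro_rate = 0.15, loss_prob = 0.1,
                              fossil_prob = 0.3, fossil_extra_divergence = 2,
                              subst_model = c("JC69", "K2P"), kappa = 2,
                              maturase_frac = 0.6, maturase_aa = 300,
                              maturase_decay = 0.15,
                              decay_events = c("stop", "frameshift",
                                               "truncation"), seed) {
  if (missing(seed) || is.na(seed)) stop("seed is mandatory", call. = FALSE)
  subst_model <- match.arg(subst_model)
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  if (is.null(tree$edge.length))
    stop("tree must have branch lengths", call. = FALSE)
  stopifnot(retro_rate >= 0, loss_prob >= 0, loss_prob <= 1,
            fossil_prob >= 0, fossil_prob <= 1,
            maturase_decay >= 0, maturase_decay <= 1, kappa > 0)
  exon_len <- exon_len + (3 - exon_len %% 3) %% 3
  structure(list(tree = tree, n_genes = n_genes,
                 exons_per_gene = exons_per_gene, exon_len = exon_len,
                 spacer_len = spacer_len,
                 n_founder_introns = n_founder_introns,
                 intron_core_len = intron_core_len, retro_rate = retro_rate,
                 loss_prob = loss_prob, fossil_prob = fossil_prob,
                 fossil_extra_divergence = fossil_extra_divergence,
                 subst_model = subst_model, kappa = kappa,
                 maturase_frac = maturase_frac, maturase_aa = maturase_aa,
                 maturase_decay = maturase_decay,
                 decay_events = decay_events, seed = as.integer(seed)),
            class = "sim_params")
}

#' Per-site substitution of a sequence under JC69 or K2P
#'
#' Applies the exact per-site substitution probabilities for the model: for
#' JC69 each site changes with probability `3/4 (1 - exp(-4 d / 3))`,
#' uniformly to one of the other bases; K2P splits that probability into the
#' closed-form transition and transversion components for the given kappa.
#'
#' @param seq nucleotide sequence.
#' @param d branch length (expected substitutions/site).
#' @param model `"JC69"` or `"K2P"`.
#' @param kappa K2P transition/transversion rate ratio.
#' @return list with `seq` (mutated), `positions` and `bases` (the draws, so
#'   a replay can reapply them without an RNG).
#' @export
mutate_seq <- function(seq, d, model = "JC69", kappa = 2) {
  if (d < 0) stop("branch length must be >= 0", call. = FALSE)
  s <- strsplit(normalize_rna(seq), "")[[1]]
  n <- length(s)
  if (d == 0 || n == 0)
    return(list(seq = paste(s, collapse = ""), positions = integer(0),
                bases = character(0)))
  transition <- c(A = "G", G = "A", C = "U", U = "C")
  if (model == "JC69") {
    p_change <- 3 / 4 * (1 - exp(-4 * d / 3))
    hit <- which(stats::runif(n) < p_change)
    newb <- vapply(hit, function(i) {
      sample(setdiff(c("A", "C", "G", "U"), s[i]), 1)
    }, character(1))
  } else {
    bt <- d / (kappa + 2)          # beta * t
    at <- kappa * bt               # alpha * t
    p_ts <- 1 / 4 + 1 / 4 * exp(-4 * bt) - 1 / 2 * exp(-2 * (at + bt))
    p_tv_each <- 1 / 4 - 1 / 4 * exp(-4 * bt)
    u <- stats::runif(n)
    kind <- ifelse(u < p_ts, "ts",
            ifelse(u < p_ts + 2 * p_tv_each, "tv", "none"))
    hit <- which(kind != "none")
    newb <- vapply(hit, function(i) {
      if (kind[i] == "ts") transition[[s[i]]]
      else sample(setdiff(c("A", "C", "G", "U"),
                          c(s[i], transition[[s[i]]])), 1)
    }, character(1))
  }
  if (length(hit) > 0) s[hit] <- newb
  list(seq = paste(s, collapse = ""), positions = hit, bases = newb)
}

# ---- genome state -----------------------------------------------------------

new_counter <- function() {
  env <- new.env()
  env$i <- 0L
  function() { env$i <- env$i + 1L; sprintf("seg%04d", env$i) }
}

make_protein <- function(aa_len, motifs) {
  aas <- setdiff(AA_LETTERS, "M")
  prot <- c("M", sample(aas, aa_len - 1, TRUE))
  for (dom in names(SIM_MOTIF_AT)) {
    pep <- motifs$motif[motifs$domain == dom][1]
    at <- max(2L, round(SIM_MOTIF_AT[[dom]] * aa_len))
    prot[at:(at + nchar(pep) - 1)] <- strsplit(pep, "")[[1]]
  }
  paste(prot, collapse = "")
}

# per-founder random domain V: structure conserved (layout, GNRA loop),
# sequence free, as in real intron families
random_domainV <- function() {
  stem1 <- random_seq(9)
  stem2 <- random_seq(5)
  loop <- paste0("G", sample(c("A","C","G","U"), 1),
                 sample(c("A","G"), 1), "A")
  make_domainV(stem1, random_seq(2), stem2, loop)
}

make_intron_seq <- function(params, with_maturase, motifs) {
  core1 <- random_seq(floor(params$intron_core_len / 2))
  core2 <- random_seq(ceiling(params$intron_core_len / 2))
  orf <- ""
  orf_meta <- NULL
  orf_start <- NA_integer_
  orf_len <- 0L
  if (with_maturase) {
    prot <- make_protein(params$maturase_aa, motifs)
    # leading in-frame stop delimits the ORF so its start is unambiguous
    orf <- paste0("UAA", revtrans(prot), "UAA")
    orf_meta <- list(protein = prot)
    orf_start <- 5L + nchar(core1) + 3L
    orf_len <- nchar(orf) - 3L
  }
  seq <- paste0("GUGCG", core1, orf, core2, random_domainV(), "AC")
  list(seq = seq, orf_start = orf_start, orf_len = orf_len, meta = orf_meta)
}

# Build the root genome: alternating spacers and genes; founder introns
# inserted at random junctions.
build_root_genome <- function(params, motifs) {
  genes <- GENE_POOL[seq_len(params$n_genes)]
  nid <- new_counter()
  segments <- list()
  add <- function(seg) segments[[length(segments) + 1L]] <<- seg
  exon_lens <- list()
  for (g in genes) {
    add(list(id = nid(), type = "spacer", gene = NA,
             seq = random_seq(params$spacer_len)))
    lens <- rep(params$exon_len, params$exons_per_gene)
    exon_lens[[g]] <- lens
    for (e in seq_len(params$exons_per_gene)) {
      # codon soup without stops so frame continuity is meaningful
      aa_len <- lens[e] / 3
      pep <- paste(sample(setdiff(AA_LETTERS, "M"), aa_len, TRUE),
                   collapse = "")
      add(list(id = nid(), type = "exon", gene = g, exon_index = e,
               seq = revtrans(pep)))
    }
  }
  add(list(id = nid(), type = "spacer", gene = NA,
           seq = random_seq(params$spacer_len)))
  state <- list(segments = segments, exon_lens = exon_lens, nid = nid)
  # founder introns
  founders <- list()
  juncs <- available_junctions(state)
  pickn <- min(params$n_founder_introns, nrow(juncs))
  sel <- juncs[sample.int(nrow(juncs), pickn), , drop = FALSE]
  for (k in seq_len(pickn)) {
    with_mat <- k <= round(params$maturase_frac * pickn)
    intr <- make_intron_seq(params, with_mat, motifs)
    site <- junction_site_label(state, sel$gene[k], sel$junction[k])
    founder_id <- sprintf("fam%02d", k)
    state <- insert_intron(state, sel$gene[k], sel$junction[k], intr$seq,
                           site = site, founder = founder_id,
                           orf_start = intr$orf_start, orf_len = intr$orf_len)
    founders[[k]] <- list(founder = founder_id, site = site,
                          maturase = with_mat,
                          protein = if (with_mat) intr$meta$protein else NA)
  }
  list(state = state, founders = founders)
}

# junctions (gene, junction index) without an intron
available_junctions <- function(state) {
  res <- list()
  for (g in names(state$exon_lens)) {
    nj <- length(state$exon_lens[[g]]) - 1L
    occupied <- integer(0)
    for (seg in state$segments)
      if (seg$type == "intron" && identical(seg$gene, g))
        occupied <- c(occupied, seg$junction)
    free <- setdiff(seq_len(nj), occupied)
    if (length(free) > 0)
      res[[length(res) + 1L]] <- data.frame(gene = g, junction = free,
                                            stringsAsFactors = FALSE)
  }
  if (length(res) == 0L)
    return(data.frame(gene = character(0), junction = integer(0)))
  do.call(rbind, res)
}

# reference position of a junction: cumulative root exon length
junction_site_label <- function(state, gene, junction) {
  pos <- sum(state$exon_lens[[gene]][seq_len(junction)])
  paste0(gene, "i", pos, "g2")
}

insert_intron <- function(state, gene, junction, seq, site, founder,
                          orf_start = NA_integer_, orf_len = 0L,
                          id = NULL) {
  segs <- state$segments
  idx <- which(vapply(segs, function(s)
    s$type == "exon" && identical(s$gene, gene) &&
      s$exon_index == junction, logical(1)))
  stopifnot(length(idx) == 1)
  newseg <- list(id = if (is.null(id)) state$nid() else id, type = "intron",
                 gene = gene, junction = junction, seq = seq, site = site,
                 founder = founder, orf_start = orf_start, orf_len = orf_len,
                 mat_state = if (orf_len > 0) "intact" else "absent")
  state$segments <- append(segs, list(newseg), after = idx)
  state
}

# ---- branchwise evolution ---------------------------------------------------

evolve_branch <- function(state, params, branch_name, d, truth_env) {
  log_event <- function(...) {
    truth_env$events[[length(truth_env$events) + 1L]] <-
      data.frame(..., stringsAsFactors = FALSE)
  }
  rec <- list()  # substitution replay records
  # 1) substitutions on every segment
  for (i in seq_along(state$segments)) {
    seg <- state$segments[[i]]
    mut <- mutate_seq(seg$seq, d, params$subst_model, params$kappa)
    state$segments[[i]]$seq <- mut$seq
    if (length(mut$positions) > 0)
      rec[[length(rec) + 1L]] <- list(branch = branch_name, id = seg$id,
                                      positions = mut$positions,
                                      bases = mut$bases)
  }
  # 2) losses (with optional fossilization)
  intron_idx <- which(vapply(state$segments, function(s) s$type == "intron",
                             logical(1)))
  lose <- intron_idx[stats::runif(length(intron_idx)) < params$loss_prob]
  for (i in sort(lose, decreasing = TRUE)) {
    seg <- state$segments[[i]]
    log_event(branch = branch_name, type = "loss", site = seg$site,
              founder = seg$founder, id = seg$id, detail = "")
    if (stats::runif(1) < params$fossil_prob) {
      fd <- params$fossil_extra_divergence * max(d, 0.02)
      fmut <- mutate_seq(seg$seq, fd, params$subst_model, params$kappa)
      fseq <- apply_indels(fmut$seq)
      spacers <- which(vapply(state$segments, function(s) s$type == "spacer",
                              logical(1)))
      tgt <- sample(spacers, 1)
      at <- sample.int(nchar(state$segments[[tgt]]$seq), 1)
      antisense <- stats::runif(1) < 0.5
      ins <- if (antisense) rna_revcomp(fseq$seq) else fseq$seq
      old <- state$segments[[tgt]]$seq
      state$segments[[tgt]]$seq <- paste0(substr(old, 1, at), ins,
                                          substr(old, at + 1, nchar(old)))
      log_event(branch = branch_name, type = "fossil", site = seg$site,
                founder = seg$founder, id = state$segments[[tgt]]$id,
                detail = sprintf("at=%d;strand=%s;seq=%s", at,
                                 if (antisense) "-" else "+", ins))
    }
    state$segments[[i]] <- NULL
  }
  # 3) retrotranspositions (iterate by id: insertions shift indices, and
  # introns gained on this branch must not retro-copy again immediately)
  intron_ids <- vapply(Filter(function(s) s$type == "intron", state$segments),
                       function(s) s$id, character(1))
  for (iid in intron_ids) {
    if (stats::runif(1) >= params$retro_rate) next
    juncs <- available_junctions(state)
    if (nrow(juncs) > 0L) {
      # new-locus occupation: never reuse an insertion site already taken in
      # any lineage, so every site traces to exactly one founder lineage
      labs <- vapply(seq_len(nrow(juncs)), function(k)
        junction_site_label(state, juncs$gene[k], juncs$junction[k]),
        character(1))
      juncs <- juncs[!labs %in% truth_env$used_sites, , drop = FALSE]
    }
    if (nrow(juncs) == 0L) next
    sel <- juncs[sample.int(nrow(juncs), 1), ]
    i <- which(vapply(state$segments, function(s) s$id == iid, logical(1)))
    seg <- state$segments[[i]]
    site <- junction_site_label(state, sel$gene, sel$junction)
    state <- insert_intron(state, sel$gene, sel$junction, seg$seq,
                           site = site, founder = seg$founder,
                           orf_start = seg$orf_start, orf_len = seg$orf_len)
    truth_env$used_sites <- c(truth_env$used_sites, site)
    newid <- state$segments[[which(vapply(state$segments, function(s)
      s$type == "intron" && identical(s$site, site), logical(1)))[1]]]$id
    log_event(branch = branch_name, type = "gain", site = site,
              founder = seg$founder, id = newid,
              detail = sprintf("source=%s;seq=%s", seg$site, seg$seq))
  }
  # 4) maturase decay
  intron_idx <- which(vapply(state$segments, function(s)
    s$type == "intron" && s$orf_len > 0, logical(1)))
  for (i in intron_idx) {
    if (stats::runif(1) >= params$maturase_decay) next
    seg <- state$segments[[i]]
    dg <- degrade_orf(seg$seq, seg$orf_start, seg$orf_len,
                      event = sample(params$decay_events, 1))
    state$segments[[i]]$seq <- dg$seq
    state$segments[[i]]$orf_len <- dg$orf_len
    state$segments[[i]]$mat_state <- dg$grade
    log_event(branch = branch_name, type = "maturase_decay", site = seg$site,
              founder = seg$founder, id = seg$id,
              detail = sprintf("event=%s;grade=%s;seq=%s", dg$event,
                               dg$grade, dg$seq))
  }
  list(state = state, mutations = rec)
}

# random small indels for fossil degeneration (geometric lengths, p = 0.5)
apply_indels <- function(seq, n_indels = 3) {
  s <- seq
  for (k in seq_len(n_indels)) {
    n <- nchar(s)
    if (n < 20) break
    len <- stats::rgeom(1, 0.5) + 1L
    at <- sample.int(n - len, 1)
    if (stats::runif(1) < 0.5) {
      s <- paste0(substr(s, 1, at), substr(s, at + len + 1, n))
    } else {
      s <- paste0(substr(s, 1, at), random_seq(len), substr(s, at + 1, n))
    }
  }
  list(seq = s)
}

#' Apply a decay event to an intron-borne maturase ORF
#'
#' Samples one decay event (premature stop, frameshift or 3' truncation),
#' applies it to the ORF region of the intron sequence and reports the
#' expected conservation grade implied by the event position relative to the
#' embedded domain layout (RT at 35%, X at 60%, En at 85% of the protein).
#'
#' @param intron_seq intron sequence.
#' @param orf_start 0-based offset of the ORF within the intron.
#' @param orf_len ORF length in nt (including stop).
#' @param event optional event type (`"stop"`, `"frameshift"`,
#'   `"truncation"`); sampled when `NULL`.
#' @param at_frac optional event position as a fraction of the ORF; sampled
#'   when `NULL`.
#' @return list with `seq`, `orf_len`, `event`, `grade` (the truth grade:
#'   `intact`, `partial`, `traces` or `absent`).
#' @export
degrade_orf <- function(intron_seq, orf_start, orf_len, event = NULL,
                        at_frac = NULL) {
  if (is.na(orf_start) || orf_len <= 0)
    return(list(seq = intron_seq, orf_len = 0L, event = "none",
                grade = "absent"))
  if (is.null(event)) event <- sample(c("stop", "frameshift", "truncation"), 1)
  if (is.null(at_frac)) at_frac <- stats::runif(1, 0.2, 0.95)
  aa_len <- (orf_len - 3) / 3
  at_aa <- max(2L, floor(at_frac * aa_len))
  at_nt <- orf_start + 3L * (at_aa - 1L)
  n <- nchar(intron_seq)
  if (event == "stop") {
    seq2 <- paste0(substr(intron_seq, 1, at_nt), "UAA",
                   substr(intron_seq, at_nt + 4, n))
    new_len <- orf_len
  } else if (event == "frameshift") {
    seq2 <- paste0(substr(intron_seq, 1, at_nt), "A",
                   substr(intron_seq, at_nt + 1, n))
    new_len <- orf_len + 1L
  } else {
    cut <- orf_start + 3L * at_aa
    seq2 <- paste0(substr(intron_seq, 1, cut),
                   substr(intron_seq, orf_start + orf_len + 1, n))
    new_len <- 3L * at_aa
  }
  # expected grade: intact part of the protein runs up to at_aa
  frac <- at_aa / aa_len
  en_end <- SIM_MOTIF_AT[["En"]] + 0.05
  x_end <- SIM_MOTIF_AT[["X"]] + 0.05
  rt_end <- SIM_MOTIF_AT[["RT"]] + 0.05
  grade <- if (frac >= en_end) "intact"
           else if (frac >= x_end) "partial"
           else if (frac >= rt_end || frac >= 0.3) "traces"
           else "absent"
  list(seq = seq2, orf_len = new_len, event = event, grade = grade)
}

# ---- emission ---------------------------------------------------------------

assemble_genome <- function(state, id) {
  seqs <- vapply(state$segments, function(s) s$seq, character(1))
  starts <- cumsum(c(0L, nchar(seqs)))[seq_along(seqs)]
  feats <- list()
  for (i in seq_along(state$segments)) {
    seg <- state$segments[[i]]
    type <- seg$type
    attrs <- if (type == "intron")
      sprintf("ID=%s;site=%s;founder=%s", seg$id, seg$site, seg$founder)
    else if (type == "exon") sprintf("ID=%s;gene=%s", seg$id, seg$gene)
    else sprintf("ID=%s", seg$id)
    feats[[i]] <- data.frame(genome = id, type = type, start = starts[i],
                             end = starts[i] + nchar(seqs[i]),
                             strand = "+", attributes = attrs,
                             stringsAsFactors = FALSE)
  }
  feats <- do.call(rbind, feats)
  # gene spans
  for (g in names(state$exon_lens)) {
    gi <- which(vapply(state$segments, function(s)
      !is.null(s$gene) && identical(s$gene, g), logical(1)))
    if (length(gi) == 0) next
    feats <- rbind(feats, data.frame(
      genome = id, type = "gene", start = starts[min(gi)],
      end = starts[max(gi)] + nchar(seqs[max(gi)]), strand = "+",
      attributes = sprintf("ID=%s", g), stringsAsFactors = FALSE))
  }
  genome_bundle(id, paste(seqs, collapse = ""), feats)
}

tip_records <- function(state, taxon, clade = taxon) {
  idx <- which(vapply(state$segments, function(s) s$type == "intron",
                      logical(1)))
  if (length(idx) == 0L) return(NULL)
  seqs <- vapply(state$segments, function(s) s$seq, character(1))
  starts <- cumsum(c(0L, nchar(seqs)))[seq_along(seqs)]
  segs <- state$segments[idx]
  intron_records(
    label = vapply(segs, function(s) s$site, character(1)),
    taxon = taxon, clade = clade, genome = taxon,
    start = starts[idx], end = starts[idx] + nchar(seqs[idx]),
    strand = "+", sequence = seqs[idx], splicing_status = "functional")
}

#' Simulate genomes with known intron-family truth
#'
#' Evolves a root genome along the tree: substitutions (JC69/K2P exact
#' per-site probabilities), intron losses (excision restoring exon
#' continuity, optionally leaving a degenerate antisense-capable fossil copy
#' in a random spacer), retrotranspositions (the current intron sequence
#' copied into a random unoccupied exon junction, founding a new insertion
#' site whose label derives from the reference exon coordinates) and
#' maturase decay. Emits per-tip annotated genomes, the pooled intron record
#' table, and a truth object (founder lineages, event log, substitution
#' replay records, presence/absence matrix).
#'
#' @param params a [simulation_params()] object.
#' @return list with `genomes` (named [genome_bundle()] list), `records`
#'   (pooled [intron_records()]), `truth` and `params`.
#' @export
simulate_introns <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  motifs <- default_motif_set()
  root <- build_root_genome(params, motifs)
  truth_env <- new.env()
  truth_env$events <- list()
  truth_env$used_sites <- vapply(root$founders, function(f) f$site,
                                 character(1))
  mutations <- list()
  tree <- ape::reorder.phylo(params$tree, "cladewise")
  ntip <- length(tree$tip.label)
  rootn <- ntip + 1L
  states <- list()
  states[[rootn]] <- root$state
  genomes <- list(); records <- list()
  # cladewise edge order guarantees parents are visited before children
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    d <- tree$edge.length[e]
    branch_name <- if (ch <= ntip) tree$tip.label[ch]
                   else paste0("node", ch - ntip)
    ev <- evolve_branch(states[[p]], params, branch_name, d, truth_env)
    states[[ch]] <- ev$state
    mutations <- c(mutations, ev$mutations)
    if (ch <= ntip) {
      tip <- tree$tip.label[ch]
      genomes[[tip]] <- assemble_genome(ev$state, tip)
      rec <- tip_records(ev$state, tip)
      if (!is.null(rec)) records[[tip]] <- rec
    }
  }
  records_all <- if (length(records) > 0) do.call(rbind, records) else NULL
  events <- if (length(truth_env$events) > 0)
    do.call(rbind, truth_env$events)
  else data.frame(branch = character(0), type = character(0),
                  site = character(0), founder = character(0),
                  id = character(0), detail = character(0))
  truth <- list(founders = root$founders, events = events,
                mutations = mutations, root_state = root$state,
                matrix = truth_matrix(records_all),
                site_founder = site_founder_map(root$founders, events))
  list(genomes = genomes, records = records_all, truth = truth,
       params = params)
}

# presence/absence matrix from pooled tip records
truth_matrix <- function(records) {
  if (is.null(records) || nrow(records) == 0L) return(NULL)
  sites <- sort(unique(records$site))
  taxa <- sort(unique(records$taxon))
  m <- matrix(0L, length(sites), length(taxa),
              dimnames = list(sites, taxa))
  for (i in seq_len(nrow(records))) m[records$site[i], records$taxon[i]] <- 1L
  m
}

# true family (founder lineage) of every site ever created
site_founder_map <- function(founders, events) {
  m <- stats::setNames(vapply(founders, function(f) f$founder, character(1)),
                       vapply(founders, function(f) f$site, character(1)))
  g <- events[events$type == "gain", , drop = FALSE]
  if (nrow(g) > 0) {
    extra <- stats::setNames(g$founder, g$site)
    m <- c(m, extra[setdiff(names(extra), names(m))])
  }
  m
}

#' Replay a simulation's event log against the root genome
#'
#' Mechanically re-applies the recorded substitutions and events (no random
#' number generation) along the tree and returns the reconstructed tip
#' genome sequences. With a faithful log these are byte-identical to the
#' emitted genomes.
#'
#' @param sim result of [simulate_introns()].
#' @return named character vector of reconstructed tip genome sequences.
#' @export
replay_truth <- function(sim) {
  params <- sim$params
  tree <- ape::reorder.phylo(params$tree, "cladewise")
  ntip <- length(tree$tip.label)
  rootn <- ntip + 1L
  states <- list()
  states[[rootn]] <- sim$truth$root_state
  out <- character(0)
  mut_by_branch <- split(sim$truth$mutations,
                         vapply(sim$truth$mutations, function(m) m$branch,
                                character(1)))
  ev <- sim$truth$events
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    branch_name <- if (ch <= ntip) tree$tip.label[ch]
                   else paste0("node", ch - ntip)
    st <- states[[p]]
    # substitutions
    for (m in mut_by_branch[[branch_name]]) {
      i <- which(vapply(st$segments, function(s) s$id == m$id, logical(1)))
      if (length(i) != 1) next
      s <- strsplit(st$segments[[i]]$seq, "")[[1]]
      s[m$positions] <- m$bases
      st$segments[[i]]$seq <- paste(s, collapse = "")
    }
    # events in log order
    bev <- ev[ev$branch == branch_name, , drop = FALSE]
    for (k in seq_len(nrow(bev))) {
      row <- bev[k, ]
      if (row$type == "loss") {
        i <- which(vapply(st$segments, function(s)
          s$type == "intron" && identical(s$site, row$site), logical(1)))
        if (length(i) >= 1) st$segments[[i[1]]] <- NULL
      } else if (row$type == "fossil") {
        det <- parse_detail(row$detail)
        i <- which(vapply(st$segments, function(s) s$id == row$id, logical(1)))
        if (length(i) == 1) {
          old <- st$segments[[i]]$seq
          at <- as.integer(det[["at"]])
          st$segments[[i]]$seq <- paste0(substr(old, 1, at), det[["seq"]],
                                         substr(old, at + 1, nchar(old)))
        }
      } else if (row$type == "gain") {
        det <- parse_detail(row$detail)
        lab <- parse_intron_label(row$site)
        junction <- junction_from_site(st, row$site)
        st <- insert_intron(st, lab$gene, junction, det[["seq"]],
                            site = row$site, founder = row$founder,
                            id = row$id)
      } else if (row$type == "maturase_decay") {
        det <- parse_detail(row$detail)
        i <- which(vapply(st$segments, function(s)
          s$type == "intron" && identical(s$site, row$site), logical(1)))
        if (length(i) >= 1) st$segments[[i[1]]]$seq <- det[["seq"]]
      }
    }
    states[[ch]] <- st
    if (ch <= ntip) {
      seqs <- vapply(st$segments, function(s) s$seq, character(1))
      out[tree$tip.label[ch]] <- paste(seqs, collapse = "")
    }
  }
  out
}

parse_detail <- function(detail) {
  parts <- strsplit(detail, ";")[[1]]
  kv <- strsplit(parts, "=")
  stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
}

junction_from_site <- function(state, site) {
  lab <- parse_intron_label(site)
  lens <- state$exon_lens[[lab$gene]]
  cum <- cumsum(lens)
  which(cum == lab$ref_position)[1]
}

#' Presence/absence matrix implied by the truth event log
#'
#' Replays gains and losses (only) along the tree to derive per-tip site
#' presence, for cross-checking against the matrix derived from the emitted
#' genomes.
#'
#' @param sim result of [simulate_introns()].
#' @return binary matrix (site x tip).
#' @export
truth_matrix_from_events <- function(sim) {
  tree <- ape::reorder.phylo(sim$params$tree, "cladewise")
  ntip <- length(tree$tip.label)
  rootn <- ntip + 1L
  founders <- vapply(sim$truth$founders, function(f) f$site, character(1))
  present <- list()
  present[[rootn]] <- founders
  ev <- sim$truth$events
  tips <- list()
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    branch_name <- if (ch <= ntip) tree$tip.label[ch]
                   else paste0("node", ch - ntip)
    cur <- present[[p]]
    bev <- ev[ev$branch == branch_name, , drop = FALSE]
    for (k in seq_len(nrow(bev))) {
      if (bev$type[k] == "loss") cur <- setdiff(cur, bev$site[k])
      if (bev$type[k] == "gain") cur <- union(cur, bev$site[k])
    }
    present[[ch]] <- cur
    if (ch <= ntip) tips[[tree$tip.label[ch]]] <- cur
  }
  sites <- sort(unique(unlist(tips)))
  m <- matrix(0L, length(sites), length(tips),
              dimnames = list(sites, names(tips)))
  for (t in names(tips)) m[tips[[t]], t] <- 1L
  m
}
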