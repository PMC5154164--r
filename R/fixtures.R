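# Deterministic synthetic fixtures: pathway collections and omics tables
# emulating a pathway/genome-database extract, so every module is testable
# without downloads. No biological realism is attempted (no mass balance);
# the point is structural realism: mixed topologies, a shared currency pool
# for side metabolites, and cross-pathway backbone duplicates.

# currency-style co-substrates guaranteeing connect/merge test cases
currency_pool <- c("ATP", "ADP", "NAD", "NADH", "NADP", "NADPH", "CoA", "Pi")

# run code with a locally seeded RNG, restoring global state afterwards
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

class_paths <- list(
  biosynthesis = c("Biosynthesis", "Amino Acid Biosynthesis"),
  degradation = c("Degradation/Utilization/Assimilation",
                  "Carbohydrate Degradation"),
  energy = c("Generation of Precursor Metabolites and Energy",
             "Fermentation"),
  other = c("Detoxification", "Antibiotic Resistance"))

#' Generate a synthetic pathway
#'
#' Each reaction gets one main substrate and one main product forming the
#' requested topology, plus 0-2 side participants drawn from a shared
#' currency-compound pool; enzyme and gene labels are synthesized. The same
#' seed always yields an identical pathway.
#'
#' @param topology `"linear"`, `"cyclic"` (needs >= 3 reactions) or
#'   `"branched"` (needs >= 3).
#' @param n_reactions Number of reactions (>= 1).
#' @param seed Integer seed.
#' @param id Pathway id.
#' @param category Placement category (decides `class_path`); one of
#'   `"biosynthesis"`, `"degradation"`, `"energy"`, `"other"`. Default
#'   `"other"`.
#' @param shared_pool Character vector of compound ids that backbone
#'   compounds may be drawn from (to create cross-pathway duplicates).
#' @param shared_rate Probability that a backbone compound is drawn from
#'   `shared_pool`.
#' @return A valid [pathway()] of the requested topology.
#' @export
generate_pathway <- function(topology = c("linear", "cyclic", "branched"),
                             n_reactions, seed = 1,
                             id = sprintf("PWY-%s-%d", topology[1], seed),
                             category = "other",
                             shared_pool = character(),
                             shared_rate = 0) {
  topology <- match.arg(topology)
  if (n_reactions < 1) stop_user("n_reactions must be >= 1")
  if (topology == "cyclic" && n_reactions < 3)
    stop_user("a cyclic pathway needs >= 3 reactions")
  if (topology == "branched" && n_reactions < 3)
    stop_user("a branched pathway needs >= 3 reactions")
  category <- match.arg(category, names(class_paths))

  with_seed(seed, {
    n <- n_reactions
    n_comp <- if (topology == "cyclic") n else n + 1
    comp_name <- function(i) {
      if (length(shared_pool) && stats::runif(1) < shared_rate)
        sample(shared_pool, 1)
      else sprintf("M-%s-%02d", id, i)
    }
    comps <- character(n_comp)
    for (i in seq_len(n_comp)) {
      repeat {
        nm <- comp_name(i)
        if (!(nm %in% comps)) break  # distinct within the pathway backbone
      }
      comps[i] <- nm
    }

    # reaction i: substrate sub_of[i] -> product i (+1 in compound index)
    sub_of <- prod_of <- integer(n)
    links <- list()
    if (topology == "linear") {
      sub_of <- seq_len(n); prod_of <- seq_len(n) + 1L
      if (n >= 2) links <- lapply(seq_len(n - 1), function(i)
        c(sprintf("R%d", i), sprintf("R%d", i + 1)))
    } else if (topology == "cyclic") {
      sub_of <- seq_len(n); prod_of <- c(seq_len(n - 1) + 1L, 1L)
      links <- lapply(seq_len(n), function(i)
        c(sprintf("R%d", i), sprintf("R%d", i %% n + 1)))
    } else {
      parent <- c(0L, vapply(2:n, function(i)
        sample.int(i - 1L, 1), 1L))
      if (all(tabulate(parent, nbins = n) <= 1))
        parent[n] <- parent[n - 1L]  # force a true branch point
      sub_of[1] <- 1L; prod_of[1] <- 2L
      next_comp <- 3L
      for (i in 2:n) {
        sub_of[i] <- prod_of[parent[i]]
        prod_of[i] <- next_comp; next_comp <- next_comp + 1L
        links[[length(links) + 1L]] <- c(sprintf("R%d", parent[i]),
                                         sprintf("R%d", i))
      }
    }

    reactions <- lapply(seq_len(n), function(i) {
      parts <- list(
        reaction_participant(comps[sub_of[i]], "substrate", "main"),
        reaction_participant(comps[prod_of[i]], "product", "main"))
      for (cur in sample(currency_pool, sample(0:2, 1))) {
        parts[[length(parts) + 1L]] <- reaction_participant(
          cur, sample(c("substrate", "product"), 1), "side")
      }
      reaction(sprintf("R%d", i), parts,
               direction = if (stats::runif(1) < 0.2) "reversible"
                           else "forward",
               enzyme_labels = sprintf("Enz-%s-%d", id, i),
               gene_ids = sprintf("g-%s-%d", id, i))
    })
    pathway(id, reactions, links = links, name = sprintf("%s pathway", id),
            class_path = class_paths[[category]])
  })
}

#' Generate a synthetic pathway collection
#'
#' Mixes topologies and categories (guaranteeing at least one biosynthesis
#' and one degradation pathway when `n_pathways >= 2`); approximately
#' `shared_compound_rate` of backbone compounds are drawn from a shared pool
#' so cross-pathway duplicate metabolites exist. Reaction ids are made
#' collection-unique by prefixing the pathway id.
#'
#' @param n_pathways Number of pathways (>= 1).
#' @param shared_compound_rate Fraction in `[0, 1]`.
#' @param seed Integer seed.
#' @return A valid [pathway_collection()].
#' @export
generate_collection <- function(n_pathways, shared_compound_rate = 0.3,
                                seed = 1) {
  if (n_pathways < 1) stop_user("n_pathways must be >= 1")
  if (shared_compound_rate < 0 || shared_compound_rate > 1)
    stop_user("shared_compound_rate must be in [0, 1]")
  with_seed(seed, {
    pool <- sprintf("SHARED-%02d", 1:10)
    topos <- rep(c("linear", "cyclic", "branched"),
                 length.out = n_pathways)
    cats <- if (n_pathways == 1) sample(names(class_paths), 1) else
      c("biosynthesis", "degradation",
        sample(names(class_paths), max(0, n_pathways - 2), replace = TRUE))
    subseeds <- sample.int(2^30, n_pathways)
    pws <- lapply(seq_len(n_pathways), function(i) {
      n_rx <- if (topos[i] == "linear") sample(1:8, 1) else sample(3:8, 1)
      pw <- generate_pathway(topos[i], n_rx, seed = subseeds[i],
                             id = sprintf("PWY%03d", i), category = cats[i],
                             shared_pool = pool,
                             shared_rate = shared_compound_rate)
      # collection-unique reaction ids
      remap <- function(rid) sprintf("%s-%s", pw$id, rid)
      pw$reactions <- lapply(pw$reactions, function(r) {
        r$id <- remap(r$id); r
      })
      pw$links <- lapply(pw$links, function(lk) c(remap(lk[1]),
                                                  remap(lk[2])))
      pw
    })
    cids <- sort(unique(unlist(lapply(pws, function(pw)
      lapply(pw$reactions, function(r)
        vapply(r$participants, function(p) p$compound_id, ""))))))
    coll <- pathway_collection(lapply(cids, compound), pws)
    stopifnot(nrow(validate_collection(coll)) == 0)
    coll
  })
}

#' Generate a synthetic omics dataset for a collection
#'
#' Rows cover approximately `coverage` of the matching entity ids (gene ids
#' for `"gene"`, compound ids for `"metabolite"`, reaction ids for
#' `"flux"`); values are standard normal draws with about 5% missing cells.
#'
#' @param collection A [pathway_collection()].
#' @param data_type `"gene"`, `"metabolite"` or `"flux"`.
#' @param n_columns Number of condition/timepoint columns (>= 1).
#' @param coverage Fraction in `(0, 1]` of entities to include.
#' @param seed Integer seed.
#' @return An [omics_dataset()].
#' @export
generate_omics <- function(collection, data_type, n_columns, coverage = 1,
                           seed = 1) {
  data_type <- match.arg(data_type, c("gene", "metabolite", "flux"))
  if (n_columns < 1) stop_user("n_columns must be >= 1")
  if (coverage <= 0 || coverage > 1)
    stop_user("coverage must be in (0, 1]")
  ids <- switch(data_type,
    gene = unlist(lapply(collection$pathways, function(pw)
      lapply(pw$reactions, function(r) r$gene_ids))),
    metabolite = vapply(collection$compounds, function(cp) cp$id, ""),
    flux = unlist(lapply(collection$pathways, function(pw)
      lapply(pw$reactions, function(r) r$id))))
  ids <- sort(unique(as.character(ids)))
  with_seed(seed, {
    take <- sort(sample(ids, max(1, ceiling(coverage * length(ids)))))
    rows <- lapply(take, function(id) {
      v <- stats::rnorm(n_columns)
      v[stats::runif(n_columns) < 0.05] <- NA
      v
    })
    names(rows) <- take
    omics_dataset(data_type, sprintf("t%d", seq_len(n_columns)), rows)
  })
}

#' Write a set of fixture files to a directory
#'
#' Writes `collection.json`, `expression.tsv` (5-timepoint gene data),
#' `abundance.tsv` (single-condition metabolite data), `flux.tsv`
#' (condition-series flux data) and `scheme.json`.
#'
#' @param dir Output directory (created if missing).
#' @param n_pathways,shared_compound_rate,seed Passed to
#'   [generate_collection()].
#' @return Invisibly, the directory path.
#' @export
write_fixture_dir <- function(dir, n_pathways = 5,
                              shared_compound_rate = 0.3, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  coll <- generate_collection(n_pathways, shared_compound_rate, seed)
  write_pathway_collection(coll, file.path(dir, "collection.json"))
  write_omics_table(generate_omics(coll, "gene", 5, 1, seed),
                    file.path(dir, "expression.tsv"), "gene")
  write_omics_table(generate_omics(coll, "metabolite", 1, 1, seed),
                    file.path(dir, "abundance.tsv"), "metabolite")
  write_omics_table(generate_omics(coll, "flux", 6, 1, seed),
                    file.path(dir, "flux.tsv"), "reaction")
  jsonlite::write_json(
    list(breakpoints = c(-2, -1, 0, 1, 2),
         colors = c("#2166ac", "#67a9cf", "#d1e5f0", "#fddbc7", "#ef8a62",
                    "#b2182b"),
         missing_color = "#c0c0c0"),
    file.path(dir, "scheme.json"), auto_unbox = TRUE)
  invisible(dir)
}
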