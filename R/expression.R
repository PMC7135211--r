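#' Build a synthetic collection of 28 immune-cell gene sets
#'
#' Returns 28 named immune-cell signatures (Bindea-style cell-type taxonomy)
#' as random, possibly overlapping subsets of a synthetic gene universe.
#' These are synthetic stand-ins: the names follow the immune cell types
#' commonly profiled by ssGSEA, but the gene memberships are simulated.
#' Three sets ("Th1 cells", "Th2 cells", "Cytotoxic cells") are the
#' designated prediction targets.
#'
#' @param n_genes size of the gene universe.
#' @param set_size genes per signature.
#' @param seed RNG seed.
#' @return A named list of character vectors of gene ids, with attribute
#'   `universe` (all gene ids).
#' @export
immune_gene_sets <- function(n_genes = 5000, set_size = 20, seed = 1L) {
  cell_types <- c(
    "Th1 cells", "Th2 cells", "Cytotoxic cells", "CD8 T cells",
    "T cells", "T helper cells", "Tcm cells", "Tem cells", "Tfh cells",
    "Th17 cells", "Tgd cells", "Treg cells", "B cells", "NK cells",
    "NK CD56dim cells", "NK CD56bright cells", "Dendritic cells",
    "iDC", "aDC", "pDC", "Macrophages", "Mast cells", "Eosinophils",
    "Neutrophils", "Monocytes", "SW480 cancer cells", "Normal mucosa",
    "Lymph vessels"
  )
  stopifnot(length(cell_types) == 28L, n_genes >= 28L * set_size)
  universe <- sprintf("GENE%05d", seq_len(n_genes))
  sets <- with_seed(derive_seed(seed, "gene-sets"), {
    lapply(cell_types, function(ct) sort(sample(universe, set_size)))
  })
  names(sets) <- cell_types
  attr(sets, "universe") <- universe
  sets
}

#' Simulate a gene-expression matrix with planted immune enrichment
#'
#' Generates a genes-by-samples expression matrix on a log-like scale
#' (baseline 8, unit-ish noise). Genes in the designated Th1, Th2 and
#' cytotoxic-T sets receive a per-sample mean shift of
#' `effect_size * latent_level`; every other signature receives a shift
#' driven by its own latent activity (standard normal per sample), so all 28
#' signatures carry signal but only the designated three track the phantom
#' cohort's immune state. Background genes are exchangeable noise.
#'
#' @param states tibble from [sample_latent_states()].
#' @param gene_sets named list of gene sets (see [immune_gene_sets()]); must
#'   contain the three designated set names.
#' @param effect_size expression shift (in noise SD units when
#'   `base_noise = 1`) per unit latent level.
#' @param base_noise SD of the per-gene, per-sample noise.
#' @param seed RNG seed.
#' @param designated named character vector mapping `th1`, `th2`, `ctl` to
#'   set names in `gene_sets`.
#' @return A numeric matrix, genes x samples, with dimnames; non-negative.
#' @export
generate_expression <- function(states, gene_sets, effect_size = 2,
                                base_noise = 1, seed = 1L,
                                designated = c(th1 = "Th1 cells",
                                               th2 = "Th2 cells",
                                               ctl = "Cytotoxic cells")) {
  stopifnot(all(c("th1", "th2", "ctl") %in% names(designated)))
  missing_sets <- setdiff(unname(designated), names(gene_sets))
  if (length(missing_sets) > 0) {
    stop("designated gene set(s) absent from the collection: ",
         paste(missing_sets, collapse = ", "), call. = FALSE)
  }
  universe <- attr(gene_sets, "universe") %||%
    sort(unique(unlist(gene_sets)))
  n <- nrow(states)
  with_seed(derive_seed(seed, "expression"), {
    baseline <- 8
    expr <- matrix(
      baseline + base_noise * rnorm(length(universe) * n),
      nrow = length(universe), ncol = n,
      dimnames = list(universe, states$sample_id)
    )
    # per-set, per-sample activity: designated sets follow the cohort
    # latents, the rest have independent standard-normal activities
    latent_of <- list(th1 = states$th1_level, th2 = states$th2_level,
                      ctl = states$ctl_level)
    for (set_name in names(gene_sets)) {
      tgt <- names(designated)[match(set_name, designated)]
      activity <- if (!is.na(tgt) && length(tgt) == 1L && tgt %in% names(latent_of)) {
        latent_of[[tgt]]
      } else {
        rnorm(n)
      }
      genes <- intersect(gene_sets[[set_name]], universe)
      expr[genes, ] <- expr[genes, ] +
        matrix(effect_size * activity, nrow = length(genes), ncol = n,
               byrow = TRUE)
    }
    pmax(expr, 0)
  })
}

#' Read and write gene sets in GMT format
#'
#' @param path file path.
#' @return `read_gmt()`: a named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(names(sets))) {
    stop("duplicate gene set names in ", path, call. = FALSE)
  }
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors of gene ids.
#' @param description optional per-set description column.
#' @export
write_gmt <- function(sets, path, description = "synthetic") {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, description, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read and write expression matrices as TSV (genes x samples)
#'
#' The TSV has a `gene_id` first column and one column per sample.
#'
#' @param path file path.
#' @return `read_expression_tsv()`: numeric matrix with gene ids as rownames.
#' @export
read_expression_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (anyDuplicated(rownames(m))) stop("duplicate gene ids in ", path, call. = FALSE)
  storage.mode(m) <- "double"
  m
}

#' @rdname read_expression_tsv
#' @param expr numeric matrix, genes x samples, with dimnames.
#' @export
write_expression_tsv <- function(expr, path) {
  df <- tibble::as_tibble(expr, rownames = "gene_id")
  readr::write_tsv(df, path)
  invisible(path)
}
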