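#' Read a GMT gene-set collection
#'
#' Parses the tab-separated GMT format used by Reactome/MSigDB exports:
#' one gene set per line, with the set name in field 1, a free-text
#' description in field 2, and member gene symbols in fields 3 onwards.
#' Duplicate genes within a set are removed, keeping the first occurrence.
#'
#' @param path Path to a GMT file.
#' @return An object of class `gmt_collection`: a list with one element per
#'   set, each a list with `name`, `description` and `genes`. File order is
#'   preserved; downstream pathway indices derive from it.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) .stopf("GMT file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      .stopf("malformed GMT line %d: expected >= 3 tab-separated fields, got %d",
             i, length(fields))
    genes <- fields[-(1:2)]
    genes <- genes[nzchar(genes)]
    sets[[i]] <- list(name = fields[[1]], description = fields[[2]],
                      genes = unique(genes))
  }
  nms <- vapply(sets, `[[`, "", "name")
  if (anyDuplicated(nms))
    .stopf("duplicate gene-set name(s) in GMT: %s",
           paste(unique(nms[duplicated(nms)]), collapse = ", "))
  names(sets) <- nms
  structure(sets, class = "gmt_collection")
}

#' Write a gene-set collection to GMT
#'
#' @param coll A `gmt_collection`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(coll, path) {
  stopifnot(inherits(coll, "gmt_collection"))
  lines <- vapply(coll, function(s)
    paste(c(s$name, s$description, s$genes), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.gmt_collection <- function(x, ...) {
  sizes <- vapply(x, function(s) length(s$genes), 0L)
  cat(sprintf("Gene-set collection: %d sets, median size %g genes\n",
              length(x), stats::median(sizes)))
  invisible(x)
}

#' Filter gene sets against a dataset's gene universe
#'
#' Intersects each set with the genes measured in a dataset and drops sets
#' with fewer surviving members than `min_genes`.  The default threshold of
#' 13 genes is the one used to define pathway modules for single-cell
#' expression models.  Matching is exact, case-sensitive string equality.
#'
#' @param coll A `gmt_collection`.
#' @param universe Character vector of measured gene symbols.
#' @param min_genes Minimum surviving set size to retain a set.
#' @return A filtered `gmt_collection`, preserving input order.
#' @export
filter_gene_sets <- function(coll, universe, min_genes = 13L) {
  stopifnot(inherits(coll, "gmt_collection"), min_genes >= 1)
  if (length(universe) == 0) .stopf("gene universe is empty")
  universe <- as.character(universe)
  out <- lapply(coll, function(s) {
    g <- s$genes[s$genes %in% universe]
    if (length(g) < min_genes) NULL
    else list(name = s$name, description = s$description, genes = g)
  })
  out <- out[!vapply(out, is.null, TRUE)]
  if (length(out) == 0)
    .stopf(paste0("no gene sets retain >= %d genes from the universe; ",
                  "lower 'min_genes'"), min_genes)
  structure(out, class = "gmt_collection")
}

#' Build the binary gene-by-pathway membership matrix
#'
#' @param coll A `gmt_collection`, already filtered against `universe`
#'   (see [filter_gene_sets()]).
#' @param universe Character vector of measured genes, defining row order.
#' @return An object of class `pathway_membership` with elements `genes`
#'   (retained genes, in universe order), `pathways`, `M` (binary genes x
#'   pathways matrix), `sizes` (column sums, the per-pathway gene counts
#'   N_p), and `unassigned` (universe genes in no retained set).  By
#'   default unassigned genes are excluded from the model input; an
#'   auxiliary dense module can route them back in (see [build_masks()]).
#' @export
build_membership <- function(coll, universe) {
  stopifnot(inherits(coll, "gmt_collection"))
  universe <- as.character(universe)
  if (anyDuplicated(universe))
    .stopf("duplicated gene names in universe: %s",
           paste(unique(universe[duplicated(universe)]), collapse = ", "))
  pathways <- vapply(coll, `[[`, "", "name")
  M <- matrix(0L, length(universe), length(coll),
              dimnames = list(universe, pathways))
  for (j in seq_along(coll)) {
    hit <- universe %in% coll[[j]]$genes
    M[hit, j] <- 1L
  }
  assigned <- rowSums(M) > 0
  sizes <- colSums(M)
  storage.mode(sizes) <- "integer"
  structure(list(
    genes = universe[assigned],
    pathways = unname(pathways),
    M = M[assigned, , drop = FALSE],
    sizes = sizes,
    unassigned = universe[!assigned]
  ), class = "pathway_membership")
}

#' @export
print.pathway_membership <- function(x, ...) {
  cat(sprintf("Pathway membership: %d genes x %d pathways (N_p: %d-%d; %d unassigned genes)\n",
              length(x$genes), length(x$pathways),
              min(x$sizes), max(x$sizes), length(x$unassigned)))
  invisible(x)
}

#' Build the assignment and separation masks of a pathway-module network
#'
#' The first encoder layer is masked by a binary *assignment* matrix that
#' connects each gene only to the hidden units of modules whose pathway
#' contains it (condition-label inputs connect to every module).  Deeper
#' layers are masked by block-diagonal *separation* matrices so that no
#' information crosses module boundaries; the decoder masks mirror the
#' encoder's block structure.  An optional auxiliary dense module is
#' connected to all genes and absorbs signal that no annotated pathway can
#' explain.
#'
#' @param membership A `pathway_membership`.
#' @param hidden_per_module Hidden units per module (default 12).
#' @param latent_per_module Latent nodes per module (1 for benchmarks,
#'   4 for richer embeddings).
#' @param n_conditions Number of condition indicator columns appended to the
#'   input (0 for an unconditional model).
#' @param dense_module If `TRUE`, append one unannotated module connected to
#'   all genes.
#' @return An object of class `pmvae_masks`: binary matrices `assignment`
#'   ((N + n_conditions) x H), `sep_enc` (H x D, block diagonal; shared by
#'   the mean and log-variance heads), `sep_dec` ((D + n_conditions) x H),
#'   `out` (H x N) and `module_out` (K x N), plus `module_slices` giving
#'   each module's hidden/latent/gene index ranges and a `meta` list with
#'   the dimensions and orderings.
#' @export
build_masks <- function(membership, hidden_per_module = 12L,
                        latent_per_module = 1L, n_conditions = 0L,
                        dense_module = FALSE) {
  stopifnot(inherits(membership, "pathway_membership"),
            hidden_per_module >= 1, latent_per_module >= 1, n_conditions >= 0)
  genes <- membership$genes
  N <- length(genes)
  Mm <- membership$M[genes, , drop = FALSE]
  module_names <- membership$pathways
  member <- lapply(seq_along(module_names), function(j) which(Mm[, j] == 1L))
  if (dense_module) {
    module_names <- c(module_names, ".dense")
    member <- c(member, list(seq_len(N)))
  }
  K <- length(module_names)
  h <- as.integer(hidden_per_module)
  l <- as.integer(latent_per_module)
  H <- K * h
  D <- K * l

  in_names <- c(genes, if (n_conditions > 0) paste0("c", seq_len(n_conditions)))
  hid_names <- paste0(rep(module_names, each = h), ".h", seq_len(h))
  assignment <- matrix(0L, N + n_conditions, H,
                       dimnames = list(in_names, hid_names))
  sep_enc <- matrix(0L, H, D)
  sep_dec <- matrix(0L, D + n_conditions, H)
  out <- matrix(0L, H, N, dimnames = list(hid_names, genes))
  module_out <- matrix(0L, K, N, dimnames = list(module_names, genes))
  module_slices <- vector("list", K)
  names(module_slices) <- module_names
  for (j in seq_len(K)) {
    hid <- ((j - 1L) * h + 1L):(j * h)
    lat <- ((j - 1L) * l + 1L):(j * l)
    assignment[member[[j]], hid] <- 1L
    sep_enc[hid, lat] <- 1L
    sep_dec[lat, hid] <- 1L
    out[hid, member[[j]]] <- 1L
    module_out[j, member[[j]]] <- 1L
    module_slices[[j]] <- list(hidden = hid, latent = lat, genes = member[[j]])
  }
  if (n_conditions > 0) {
    assignment[N + seq_len(n_conditions), ] <- 1L
    sep_dec[D + seq_len(n_conditions), ] <- 1L
  }
  latent_names <- unlist(lapply(module_names, function(nm)
    if (l == 1L) nm else paste0(nm, ".", seq_len(l))))
  structure(list(
    assignment = assignment, sep_enc = sep_enc, sep_dec = sep_dec,
    out = out, module_out = module_out, module_slices = module_slices,
    meta = list(genes = genes, modules = module_names,
                latent_names = latent_names,
                N = N, K = K, hidden_per_module = h, latent_per_module = l,
                H = H, D = D, n_conditions = as.integer(n_conditions),
                dense_module = dense_module)
  ), class = "pmvae_masks")
}

#' @export
print.pmvae_masks <- function(x, ...) {
  m <- x$meta
  cat(sprintf(
    "pmVAE masks: %d genes -> %d modules x %d hidden -> %d latent nodes (%d conditions%s)\n",
    m$N, m$K, m$hidden_per_module, m$D, m$n_conditions,
    if (m$dense_module) ", incl. dense module" else ""))
  invisible(x)
}

#' Export membership or masks as TSV for inspection
#'
#' @param x A `pathway_membership` or `pmvae_masks` object.
#' @param path Output TSV path.  For masks, the assignment matrix is
#'   written.
#' @return `path`, invisibly.
#' @export
write_mask_tsv <- function(x, path) {
  m <- if (inherits(x, "pathway_membership")) x$M
       else if (inherits(x, "pmvae_masks")) x$assignment
       else .stopf("unsupported object of class %s", class(x)[1])
  utils::write.table(m, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}
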