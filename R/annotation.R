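#' Probe manifest and CpG-island geometry
#'
#' A probe manifest is a plain `data.frame` with one row per array probe and
#' the columns
#' \describe{
#'   \item{probe_id}{unique probe identifier (character)}
#'   \item{chromosome}{chromosome name, `NA` for control probes}
#'   \item{position}{1-based genomic coordinate, `NA` for control probes}
#'   \item{island_id}{identifier of the island the probe belongs to or is
#'     nearest to, `NA` for open-sea and control probes}
#'   \item{region_class}{one of `"island"`, `"shore"`, `"shelf"`,
#'     `"open_sea"`; `NA` for control probes}
#'   \item{gene_symbols}{semicolon-separated gene symbols (may be `""`)}
#'   \item{feature_context}{semicolon-separated genomic features, e.g.
#'     `"TSS_window;first_exon"`}
#'   \item{cross_reactive, is_sex_chromosome, is_negative_control,
#'     is_internal_control}{logical flags}
#' }
#' Island intervals are a companion `data.frame` with columns `island_id`,
#' `chromosome`, `start`, `end` (1-based, closed) and `gene_symbols`.
#'
#' Region classes follow the usual array annotation convention: a probe is in
#' a *shore* when it lies within 2 kb of an island edge, in a *shelf* between
#' 2 and 3 kb, and in the *open sea* beyond 3 kb.
#'
#' @param manifest a probe manifest `data.frame`.
#' @return `validate_manifest()` returns the manifest invisibly, or stops
#'   with an informative error.
#' @export
validate_manifest <- function(manifest) {
  required <- c("probe_id", "chromosome", "position", "island_id",
                "region_class", "gene_symbols", "feature_context",
                "cross_reactive", "is_sex_chromosome",
                "is_negative_control", "is_internal_control")
  missing <- setdiff(required, names(manifest))
  if (length(missing) > 0)
    stop("manifest is missing columns: ", paste(missing, collapse = ", "))
  if (anyDuplicated(manifest$probe_id))
    stop("manifest probe_id values must be unique")
  ctrl <- manifest$is_negative_control | manifest$is_internal_control
  bad <- !ctrl & (is.na(manifest$chromosome) | is.na(manifest$position) |
                    manifest$position <= 0)
  if (any(bad))
    stop("non-control probes must have a chromosome and a positive position (",
         sum(bad), " offending probes)")
  if (any(!is.na(manifest$region_class[ctrl])))
    stop("control probes must not carry genomic annotation")
  invisible(manifest)
}

#' Classify a genomic position relative to CpG islands
#'
#' Returns `"island"` if the position falls inside any island interval,
#' otherwise `"shore"`, `"shelf"` or `"open_sea"` by distance to the nearest
#' island edge (1--2000 bp, 2001--3000 bp, > 3000 bp respectively).
#' Coordinates are 1-based and intervals closed; containment counts as
#' distance zero.
#'
#' @param position integer genomic position (>= 1).
#' @param islands `data.frame` of island intervals on the same chromosome,
#'   with columns `start` and `end`. An empty frame yields `"open_sea"`.
#' @return a single string: the region class.
#' @examples
#' isl <- data.frame(island_id = "I1", chromosome = "chr1",
#'                   start = 400, end = 600, gene_symbols = "G1")
#' classify_region(500, isl)   # "island"
#' classify_region(2599, isl)  # "shore"
#' classify_region(3100, isl)  # "shelf"
#' @export
classify_region <- function(position, islands) {
  if (length(position) != 1L || is.na(position) || position < 1)
    stop("position must be a single coordinate >= 1")
  if (is.null(islands) || nrow(islands) == 0L) return("open_sea")
  if (any(islands$start > islands$end))
    stop("malformed island interval: start > end")
  if (any(position >= islands$start & position <= islands$end))
    return("island")
  d <- pmin(abs(position - islands$start), abs(position - islands$end))
  d <- min(d)
  if (d <= 2000) "shore" else if (d <= 3000) "shelf" else "open_sea"
}

# split a semicolon-separated symbol column into a list of character vectors
split_symbols <- function(x) {
  out <- strsplit(ifelse(is.na(x), "", x), ";", fixed = TRUE)
  lapply(out, function(s) unique(s[nzchar(s)]))
}

#' Map genes to their island and shore probes
#'
#' Collects, for every gene symbol in the manifest, the probes annotated to
#' it that lie in a CpG island or island shore (shelf and open-sea probes are
#' excluded, as are control, cross-reactive and sex-chromosome probes unless
#' `use_filtered` supplies a pre-filtered probe universe). Genes with fewer
#' than `min_probes` qualifying probes are dropped and reported: a paired
#' signed-rank test on a shorter probe vector is uninformative.
#'
#' Probes annotated to several genes contribute to each of them.
#'
#' @param manifest a validated probe manifest.
#' @param min_probes minimum island+shore probes for a gene to be testable.
#' @param probe_universe optional character vector of probe ids to restrict
#'   to (e.g. the QC-retained set); defaults to all manifest probes.
#' @return a list with elements `map` (named list, gene -> sorted character
#'   vector of probe ids) and `excluded` (`data.frame` of dropped genes and
#'   their probe counts).
#' @export
build_gene_island_map <- function(manifest, min_probes = 3,
                                  probe_universe = NULL) {
  validate_manifest(manifest)
  keep <- !manifest$is_negative_control & !manifest$is_internal_control &
    manifest$region_class %in% c("island", "shore")
  if (!is.null(probe_universe))
    keep <- keep & manifest$probe_id %in% probe_universe
  m <- manifest[keep, , drop = FALSE]
  genes <- split_symbols(m$gene_symbols)
  n_per <- lengths(genes)
  if (sum(n_per) == 0L)
    return(list(map = list(),
                excluded = data.frame(gene = character(), n_probes = integer())))
  long <- data.frame(gene = unlist(genes),
                     probe_id = rep(m$probe_id, n_per),
                     stringsAsFactors = FALSE)
  map <- lapply(split(long$probe_id, long$gene), function(p) sort(unique(p)))
  sizes <- lengths(map)
  excluded <- data.frame(gene = names(map)[sizes < min_probes],
                         n_probes = unname(sizes[sizes < min_probes]))
  list(map = map[sizes >= min_probes], excluded = excluded)
}

#' Genomic-feature composition of a probe set
#'
#' Tabulates, for each region class and each annotated feature context, how
#' many probes of `probe_set` fall in it, which fraction of the set that is,
#' and which fraction of all array probes carrying that feature are in the
#' set. Probes may carry several feature contexts, so feature fractions need
#' not sum to one; the four region classes are mutually exclusive and their
#' set-fractions do sum to one over any non-empty set.
#'
#' @param probe_set character vector of probe ids (must be manifest probes).
#' @param manifest a validated probe manifest.
#' @return a `data.frame` with columns `feature`, `kind` (`"region"` or
#'   `"context"`), `count`, `fraction_of_set`, `fraction_of_feature`.
#' @export
annotate_feature_fractions <- function(probe_set, manifest) {
  validate_manifest(manifest)
  ann <- manifest[!manifest$is_negative_control & !manifest$is_internal_control, ]
  if (!all(probe_set %in% ann$probe_id))
    stop("probe_set contains ids not present in the manifest")
  in_set <- ann$probe_id %in% probe_set
  n_set <- sum(in_set)

  region_levels <- c("island", "shore", "shelf", "open_sea")
  ctx <- split_symbols(ann$feature_context)
  ctx_levels <- sort(unique(unlist(ctx)))

  one <- function(feature, kind, member) {
    cnt <- sum(member & in_set)
    data.frame(feature = feature, kind = kind, count = cnt,
               fraction_of_set = if (n_set > 0) cnt / n_set else 0,
               fraction_of_feature = if (sum(member) > 0) cnt / sum(member) else 0)
  }
  rows <- c(
    lapply(region_levels, function(rc) one(rc, "region", ann$region_class == rc)),
    lapply(ctx_levels, function(fc)
      one(fc, "context", vapply(ctx, function(s) fc %in% s, logical(1))))
  )
  do.call(rbind, rows)
}

#' Read / write manifest and island tables
#'
#' Tab-separated plain-text serialisation of the probe manifest and island
#' interval table, one probe (island) per row.
#'
#' @param manifest,islands the objects to write.
#' @param path file path.
#' @return the read functions return the corresponding `data.frame`.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.table(manifest, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = c(probe_id = "character"))
  for (col in c("gene_symbols", "feature_context")) m[[col]][is.na(m[[col]])] <- ""
  validate_manifest(m)
  m
}

#' @rdname write_manifest
#' @export
write_islands <- function(islands, path) {
  utils::write.table(islands, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_islands <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
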