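# Readers and writers for the external formats. One coordinate convention
# everywhere: 1-based, inclusive, matching GFF3. An insertion site is the
# coordinate to which the 5' end of a read mapped; strand is ignored.

#' Construct an insertion profile
#'
#' An insertion profile holds one sample's map from (replicon, position) to
#' read count. Positions are 1-based; duplicate (replicon, position) keys
#' are not allowed (readers merge them by summing before construction).
#'
#' @param sample_id Sample identifier.
#' @param sites A data.frame with columns `replicon`, `position`, `count`.
#' @return An object of class `insertion_profile`.
#' @export
insertion_profile <- function(sample_id, sites) {
  stopifnot(is.character(sample_id), length(sample_id) == 1L)
  sites <- as.data.frame(sites)[, c("replicon", "position", "count")]
  sites$replicon <- as.character(sites$replicon)
  sites$position <- as.numeric(sites$position)
  sites$count <- as.numeric(sites$count)
  if (nrow(sites) > 0) {
    if (any(sites$position < 1 | sites$position != floor(sites$position)))
      stop("insertion positions must be integers >= 1 (1-based convention)")
    if (any(sites$count < 0))
      stop("read counts must be non-negative")
    key <- paste(sites$replicon, sites$position)
    if (anyDuplicated(key))
      stop("duplicate (replicon, position) keys in insertion profile")
    o <- order(sites$replicon, sites$position)
    sites <- sites[o, , drop = FALSE]
    rownames(sites) <- NULL
  }
  structure(list(sample_id = sample_id, sites = sites),
            class = "insertion_profile")
}

#' @export
print.insertion_profile <- function(x, ...) {
  cat(sprintf("<insertion_profile> sample '%s': %d sites, %.0f reads on %d replicon(s)\n",
              x$sample_id, nrow(x$sites), total_count(x),
              length(unique(x$sites$replicon))))
  invisible(x)
}

#' Total read count of an insertion profile
#' @param profile An `insertion_profile`.
#' @return Sum of per-site counts.
#' @export
total_count <- function(profile) sum(profile$sites$count)

#' Read a per-sample insertion-site table
#'
#' Supports two dialects: a plain TSV with columns
#' `replicon  position  count` (`#` comments and an optional header line
#' allowed), and a wiggle file with `variableStep`/`fixedStep` blocks as
#' produced by common TnSeq preprocessors. Duplicate (replicon, position)
#' rows are summed with a warning: merged sequencing runs of the same
#' library legitimately produce them.
#'
#' @param path Path to the file.
#' @param dialect `"auto"` (by extension), `"tsv"` or `"wig"`.
#' @param sample_id Sample identifier; defaults to the file name without
#'   extension.
#' @return An [insertion_profile()].
#' @export
read_insertion_table <- function(path, dialect = c("auto", "tsv", "wig"),
                                 sample_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sample_id))
    sample_id <- tools::file_path_sans_ext(basename(path))
  if (dialect == "auto")
    dialect <- if (grepl("\\.wig$", path, ignore.case = TRUE)) "wig" else "tsv"
  sites <- if (dialect == "wig") .read_sites_wig(path) else .read_sites_tsv(path)
  key <- paste(sites$replicon, sites$position)
  if (anyDuplicated(key)) {
    n_dup <- sum(duplicated(key))
    warning(sprintf("%d duplicate (replicon, position) rows in '%s' summed",
                    n_dup, basename(path)))
    agg <- rowsum(sites$count, key, reorder = FALSE)
    first <- !duplicated(key)
    sites <- data.frame(replicon = sites$replicon[first],
                        position = sites$position[first],
                        count = agg[match(key[first], rownames(agg)), 1])
  }
  insertion_profile(sample_id, sites)
}

.read_sites_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0)
    return(data.frame(replicon = character(), position = numeric(),
                      count = numeric()))
  fields <- strsplit(lines, "[\t ]+")
  nf <- lengths(fields)
  if (any(nf != 3L))
    stop(sprintf("malformed insertion table line %d in '%s': expected 3 fields, got %d",
                 lineno[which(nf != 3L)[1]], basename(path), nf[nf != 3L][1]))
  m <- do.call(rbind, fields)
  # optional header row: non-numeric position field
  if (is.na(suppressWarnings(as.numeric(m[1, 2])))) {
    m <- m[-1, , drop = FALSE]
    lineno <- lineno[-1]
  }
  if (nrow(m) == 0)
    return(data.frame(replicon = character(), position = numeric(),
                      count = numeric()))
  pos <- suppressWarnings(as.numeric(m[, 2]))
  cnt <- suppressWarnings(as.numeric(m[, 3]))
  bad <- which(is.na(pos) | is.na(cnt))
  if (length(bad))
    stop(sprintf("malformed insertion table line %d in '%s': non-numeric field",
                 lineno[bad[1]], basename(path)))
  if (any(pos == 0))
    stop(sprintf("position 0 at line %d of '%s': positions are 1-based",
                 lineno[which(pos == 0)[1]], basename(path)))
  if (any(pos < 1 | pos != floor(pos)))
    stop(sprintf("invalid position at line %d of '%s'",
                 lineno[which(pos < 1 | pos != floor(pos))[1]], basename(path)))
  if (any(cnt < 0))
    stop(sprintf("negative read count at line %d of '%s'",
                 lineno[which(cnt < 0)[1]], basename(path)))
  data.frame(replicon = m[, 1], position = pos, count = cnt)
}

.read_sites_wig <- function(path) {
  gr <- rtracklayer::import(path, format = "wig")
  cnt <- as.numeric(S4Vectors::mcols(gr)$score)
  if (any(cnt < 0)) stop("negative read count in wig file '", basename(path), "'")
  data.frame(replicon = as.character(GenomicRanges::seqnames(gr)),
             position = GenomicRanges::start(gr),
             count = cnt)
}

#' Write an insertion profile to disk
#'
#' @param profile An [insertion_profile()].
#' @param path Output path.
#' @param dialect `"tsv"` or `"wig"` (variableStep blocks, span 1).
#' @return `path`, invisibly.
#' @export
write_insertion_table <- function(profile, path, dialect = c("tsv", "wig")) {
  dialect <- match.arg(dialect)
  s <- profile$sites
  if (dialect == "tsv") {
    out <- data.frame(replicon = s$replicon, position = s$position,
                      count = s$count)
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    for (rep in unique(s$replicon)) {
      sub <- s[s$replicon == rep, , drop = FALSE]
      writeLines(sprintf("variableStep chrom=%s", rep), con)
      writeLines(sprintf("%d %s", as.integer(sub$position),
                         format(sub$count, trim = TRUE, scientific = FALSE)),
                 con)
    }
  }
  invisible(path)
}

#' Read a gene annotation
#'
#' Accepts GFF3 (features of type `gene` or `CDS` carrying a `locus_tag`
#' attribute; COG letters read from an optional `cog` attribute, product
#' from `product`) or a flat TSV with columns
#' `locus_tag replicon start end strand cog product` (last two optional).
#' Coordinates are 1-based inclusive and preserved exactly.
#'
#' @param path Path to the annotation file.
#' @param format `"auto"` (by extension), `"gff3"` or `"tsv"`.
#' @return A data.frame with columns `locus_tag`, `replicon`, `start`,
#'   `end`, `strand`, `length`, `cog` (string of single-letter COG codes,
#'   possibly empty) and `product`.
#' @export
read_annotation <- function(path, format = c("auto", "gff3", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3" else "tsv"
  genes <- if (format == "gff3") .read_annotation_gff3(path) else
    .read_annotation_tsv(path)
  .validate_genes(genes)
}

.read_annotation_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  keep <- mc$type %in% c("gene", "CDS")
  gr <- gr[keep]
  mc <- S4Vectors::mcols(gr)
  if (is.null(mc$locus_tag) || any(is.na(mc$locus_tag)))
    stop("GFF3 gene/CDS features must carry a locus_tag attribute")
  lt <- as.character(mc$locus_tag)
  # prefer 'gene' rows when a locus_tag has both gene and CDS features
  ord <- order(match(as.character(mc$type), c("gene", "CDS")))
  first <- ord[!duplicated(lt[ord])]
  gr <- gr[first]; mc <- S4Vectors::mcols(gr)
  cog <- if (!is.null(mc$cog)) as.character(mc$cog) else ""
  cog[is.na(cog)] <- ""
  product <- if (!is.null(mc$product)) as.character(mc$product) else ""
  product[is.na(product)] <- ""
  data.frame(locus_tag = as.character(mc$locus_tag),
             replicon = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             cog = cog, product = product)
}

.read_annotation_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("locus_tag", "replicon", "start", "end", "strand")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("annotation TSV missing column(s): ", paste(miss, collapse = ", "))
  if (is.null(df$cog)) df$cog <- ""
  if (is.null(df$product)) df$product <- ""
  df$cog[is.na(df$cog)] <- ""
  df$product[is.na(df$product)] <- ""
  df[, c(need, "cog", "product")]
}

.validate_genes <- function(genes) {
  genes$locus_tag <- as.character(genes$locus_tag)
  genes$replicon <- as.character(genes$replicon)
  genes$start <- as.numeric(genes$start)
  genes$end <- as.numeric(genes$end)
  genes$strand <- as.character(genes$strand)
  if (any(genes$start > genes$end))
    stop("annotation has start > end for: ",
         paste(genes$locus_tag[genes$start > genes$end], collapse = ", "))
  if (!all(genes$strand %in% c("+", "-", "*")))
    stop("strand must be '+' or '-'")
  dup <- unique(genes$locus_tag[duplicated(genes$locus_tag)])
  if (length(dup))
    stop("duplicate locus_tag(s) in annotation: ", paste(dup, collapse = ", "))
  genes$length <- genes$end - genes$start + 1
  rownames(genes) <- NULL
  genes[, c("locus_tag", "replicon", "start", "end", "strand", "length",
            "cog", "product")]
}

#' Write a gene annotation as flat TSV
#' @param genes Annotation data.frame as returned by [read_annotation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(genes, path) {
  out <- genes[, c("locus_tag", "replicon", "start", "end", "strand",
                   "cog", "product")]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' COG category letters per gene
#' @param genes Annotation data.frame.
#' @return Named list of character vectors (possibly empty) of COG letters.
#' @export
cog_categories <- function(genes) {
  out <- strsplit(gsub("[^A-Z]", "", toupper(genes$cog)), "")
  names(out) <- genes$locus_tag
  out
}

#' Read a sample sheet
#'
#' CSV or TSV (delimiter auto-detected from the header line) with required
#' columns `sample_id` and `condition`, optional `mapped_fraction` (fraction
#' of reads mapping to the target organism, in \[0, 1\]) and `include`
#' (defaults to `TRUE` when absent).
#'
#' @param path Path to the sheet.
#' @return A data.frame with columns `sample_id`, `condition`,
#'   `mapped_fraction` (NA when not given) and `include`.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- read.delim(path, sep = sep, stringsAsFactors = FALSE)
  need <- c("sample_id", "condition")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("sample sheet missing column(s): ", paste(miss, collapse = ", "))
  if (is.null(df$mapped_fraction)) df$mapped_fraction <- NA_real_
  df$mapped_fraction <- as.numeric(df$mapped_fraction)
  if (any(!is.na(df$mapped_fraction) &
          (df$mapped_fraction < 0 | df$mapped_fraction > 1)))
    stop("mapped_fraction must lie in [0, 1]")
  if (is.null(df$include)) df$include <- TRUE
  if (!is.logical(df$include))
    df$include <- tolower(as.character(df$include)) %in%
      c("true", "t", "1", "yes", "y")
  df$sample_id <- as.character(df$sample_id)
  df$condition <- as.character(df$condition)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id(s) in sample sheet: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  df[, c("sample_id", "condition", "mapped_fraction", "include")]
}

#' Write a sample sheet
#' @param sheet Sample sheet data.frame.
#' @param path Output path (TSV).
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(sheet, path) {
  write.table(sheet, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a per-gene comparison results table
#'
#' Rows are ordered by `locus_tag` and columns canonically; numeric fields
#' are written at full double precision so a write/read round trip is
#' lossless well beyond 12 significant digits. Infinite log2 fold changes
#' serialize as `Inf`/`-Inf` and parse back as infinities.
#'
#' @param results A `ComparisonResult` data.frame from [compare_conditions()].
#' @param path Output path (TSV).
#' @return `path`, invisibly.
#' @export
write_results_table <- function(results, path) {
  if (is.null(results) || nrow(results) == 0)
    stop("results table is empty; nothing to write")
  cols <- .result_columns()
  cols <- cols[cols %in% names(results)]
  out <- results[order(results$locus_tag), cols, drop = FALSE]
  ok <- tryCatch({
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write results table to '", path, "': ",
                        conditionMessage(ok))
  invisible(path)
}

#' Read back a comparison results table written by [write_results_table()]
#' @param path Path to the TSV.
#' @return The results data.frame.
#' @export
read_results_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  for (col in intersect(c("log2fc_hit", "influential", "sig05", "sig01",
                          "welch_degenerate", "consensus_all3",
                          "consensus_cooks_welch"), names(df)))
    df[[col]] <- as.logical(df[[col]])
  df
}

.result_columns <- function() {
  c("locus_tag", "mean_ED_A", "mean_ED_B", "log2FC", "log2fc_hit",
    "cooksD", "influential", "welch_t", "welch_df", "welch_p", "p_adj",
    "sig05", "sig01", "welch_degenerate", "direction",
    "consensus_all3", "consensus_cooks_welch")
}
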