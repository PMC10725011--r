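# COG functional-category tallies over hit sets. Every hit gene
# contributes one count to every category letter it carries; the pseudo
# categories mirror the common reporting convention: R = general function
# prediction, S = function unknown, and genes with no COG assignment are
# binned as hypothetical.

.COG_PSEUDO <- c(R = "general_function", S = "unknown_function")

#' Tally COG categories over a hit set
#'
#' Each gene contributes one count to every COG category it carries, so
#' the total number of predictions can exceed the number of genes.
#' Uncategorized genes are counted as `hypothetical`; the letters R and S
#' are reported as the pseudo-categories `general_function` and
#' `unknown_function`.
#'
#' @param hit_genes Character vector of locus tags (must all be present in
#'   the annotation).
#' @param genes Annotation data.frame with a `cog` column.
#' @param pseudo_map Named character vector mapping COG letters to
#'   pseudo-category names; defaults to `c(R = "general_function",
#'   S = "unknown_function")`.
#' @return A data.frame `category`, `count` sorted by decreasing count,
#'   with attributes `total_predictions` and `total_genes`.
#' @export
tally_cog <- function(hit_genes, genes, pseudo_map = .COG_PSEUDO) {
  hit_genes <- unique(as.character(hit_genes))
  missing <- setdiff(hit_genes, genes$locus_tag)
  if (length(missing))
    stop("hit gene(s) absent from annotation: ",
         paste(missing, collapse = ", "))
  cats <- cog_categories(genes)[hit_genes]
  per_gene <- lapply(cats, function(letters) {
    if (length(letters) == 0) return("hypothetical")
    out <- letters
    renamed <- out %in% names(pseudo_map)
    out[renamed] <- pseudo_map[out[renamed]]
    unique(out)
  })
  counts <- table(unlist(per_gene))
  out <- data.frame(category = as.character(names(counts)),
                    count = as.integer(counts))
  if (nrow(out) == 0)
    out <- data.frame(category = character(), count = integer())
  out <- out[order(-out$count, out$category), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "total_predictions") <- sum(out$count)
  attr(out, "total_genes") <- length(hit_genes)
  out
}

#' Write COG tallies for several hit sets
#' @param tallies Named list of data.frames from [tally_cog()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_cog_tallies <- function(tallies, path) {
  rows <- do.call(rbind, lapply(names(tallies), function(nm) {
    t <- tallies[[nm]]
    if (nrow(t) == 0)
      return(data.frame(hit_set = character(), category = character(),
                        count = integer()))
    data.frame(hit_set = nm, category = t$category, count = t$count)
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
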