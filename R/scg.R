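#' Load a single-copy-gene collection
#'
#' A collection is an ordered set of unique gene identifiers. The bundled
#' default is the 139-gene bacterial single-copy collection of Campbell et
#' al., shipped as a names file; the HMM profiles themselves are not
#' redistributed — point [parse_hmm_tblout()] at your own hmmsearch output
#' against that collection. The census depends only on the identifiers
#' matching between the hit table and the collection.
#'
#' @param path Path to a names file (one gene identifier per line, `#`
#'   comments allowed); default is the bundled bacterial collection.
#' @param name Collection label.
#' @return An `scg_collection`: character vector of gene identifiers with
#'   a `name` attribute.
#' @export
scg_collection <- function(path = NULL, name = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "bacterial_scg_139.txt",
                        package = "scafscreen", mustWork = TRUE)
    if (is.null(name)) name <- "bacterial_139"
  }
  genes <- readLines(path)
  genes <- trimws(genes)
  genes <- genes[nzchar(genes) & !startsWith(genes, "#")]
  if (length(genes) == 0) stop("empty gene collection: ", path)
  if (anyDuplicated(genes)) stop("duplicate gene identifiers in collection")
  structure(genes, name = if (is.null(name)) basename(path) else name,
            class = "scg_collection")
}

#' Parse single-copy-gene hits
#'
#' Accepts either hmmsearch `--tblout` output (whitespace-separated, `#`
#' comment lines; target = split, query = gene, column 5 = full-sequence
#' e-value) or a plain 3-column TSV `gene, split_name, evalue` (header
#' optional). Hits above the e-value cutoff are dropped; hits to genes not
#' in the collection are skipped with a warning.
#'
#' @param path Path to the hit file.
#' @param collection An `scg_collection`.
#' @param evalue_max Significance cutoff on the e-value (default 1e-10).
#' @return An `scg_hits` data.frame with columns `gene`, `split_name`,
#'   `evalue`, and attribute `evalue_max`.
#' @export
parse_hmm_tblout <- function(path, collection, evalue_max = 1e-10) {
  stopifnot(inherits(collection, "scg_collection"))
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) {
    return(new_scg_hits(data.frame(gene = character(), split_name = character(),
                                   evalue = numeric()), evalue_max))
  }
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  parse_row <- function(f, ln) {
    if (length(f) >= 18) {
      # hmmsearch --tblout: target(1) tacc(2) query(3) qacc(4) evalue(5) ...
      c(gene = f[3], split_name = f[1], evalue = f[5])
    } else if (length(f) == 3) {
      c(gene = f[1], split_name = f[2], evalue = f[3])
    } else {
      stop("unparseable hit line ", ln, " in '", path, "' (",
           length(f), " fields)")
    }
  }
  rows <- mapply(parse_row, fields, lineno, SIMPLIFY = FALSE)
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  # tolerate a TSV header row
  if (nf[1] == 3 && is.na(suppressWarnings(as.numeric(df$evalue[1]))) &&
      tolower(df$gene[1]) == "gene") {
    df <- df[-1, , drop = FALSE]
    lineno <- lineno[-1]
  }
  ev <- suppressWarnings(as.numeric(df$evalue))
  if (anyNA(ev) && nrow(df) > 0) {
    stop("non-numeric e-value at line ", lineno[which(is.na(ev))[1]],
         " in '", path, "'")
  }
  df$evalue <- ev
  df <- df[df$evalue <= evalue_max, , drop = FALSE]
  foreign <- setdiff(unique(df$gene), collection)
  if (length(foreign) > 0) {
    warning(length(foreign), " gene name(s) not in collection '",
            attr(collection, "name"), "' skipped: ",
            paste(head(foreign, 5), collapse = ", "))
    df <- df[df$gene %in% collection, , drop = FALSE]
  }
  rownames(df) <- NULL
  new_scg_hits(df, evalue_max)
}

new_scg_hits <- function(df, evalue_max) {
  structure(df, evalue_max = evalue_max,
            class = c("scg_hits", "data.frame"))
}

#' Census of single-copy-gene hits
#'
#' Counts hits per gene (each hit row counts once — tandem copies are
#' genuine extra copies) and estimates the number of complete bacterial
#' genomes in the scaffold collection as the mode (most frequently
#' occurring value) of the per-gene hit-count array. When several values
#' tie for the maximal frequency the smallest is returned and the census
#' is flagged multimodal — conservative, so contamination is not
#' overstated.
#'
#' @param hits An `scg_hits` table.
#' @param collection The `scg_collection` the hits were searched against.
#' @param subset Optional character vector of split names restricting the
#'   census (e.g. the splits of one bin); NULL censuses everything.
#' @return An `scg_census`: list with `hit_counts` (named integer vector
#'   in collection order), `estimated_genomes`, `multimodal`, and
#'   `evalue_max`.
#' @export
census <- function(hits, collection, subset = NULL) {
  stopifnot(inherits(collection, "scg_collection"))
  df <- as.data.frame(hits)
  if (!is.null(subset)) df <- df[df$split_name %in% subset, , drop = FALSE]
  counts <- table(factor(df$gene, levels = as.character(collection)))
  counts <- setNames(as.integer(counts), names(counts))
  freq <- table(counts)
  top <- as.integer(names(freq)[freq == max(freq)])
  structure(list(hit_counts = counts,
                 estimated_genomes = min(top),
                 multimodal = length(top) > 1,
                 evalue_max = attr(hits, "evalue_max")),
            class = "scg_census")
}

#' @export
print.scg_census <- function(x, ...) {
  cat("scg_census over", length(x$hit_counts), "genes:",
      "estimated_bacterial_genomes:", x$estimated_genomes,
      "(multimodal:", x$multimodal, ")\n")
  invisible(x)
}

#' Completeness and redundancy of a genome bin
#'
#' Completeness is the percentage of collection genes hit at least once in
#' the bin; redundancy the percentage hit more than once. These proxy the
#' completion and contamination of a bin: a coherent near-complete
#' bacterial genome approaches 100% completeness with low redundancy.
#'
#' @param hits An `scg_hits` table.
#' @param collection The `scg_collection`.
#' @param bin_splits Character vector of the bin's split names.
#' @return Named numeric vector `c(completeness =, redundancy =)`, in
#'   percent.
#' @export
bin_completeness_redundancy <- function(hits, collection, bin_splits) {
  cs <- census(hits, collection, subset = bin_splits)
  n <- length(collection)
  c(completeness = 100 * sum(cs$hit_counts >= 1) / n,
    redundancy = 100 * sum(cs$hit_counts >= 2) / n)
}

#' Square-root-normalized occurrence report
#'
#' Summarizes one or more censuses (e.g. raw assembly vs curated genome)
#' as a long table and companion plots: one bar panel per census with bar
#' heights `sqrt(hit_count)` per gene, and a box-plot summary of the
#' per-gene counts per census.
#'
#' @param censuses Named list of `scg_census` objects (names label the
#'   panels).
#' @return List with `table` (data.frame `label`, `gene`, `hit_count`,
#'   `sqrt_hit_count`), `bar_plot` and `box_plot` (ggplot objects).
#' @export
occurrence_report <- function(censuses) {
  stopifnot(length(censuses) >= 1)
  if (is.null(names(censuses)) || any(!nzchar(names(censuses)))) {
    stop("censuses must be a named list")
  }
  tab <- do.call(rbind, lapply(names(censuses), function(lb) {
    hc <- censuses[[lb]]$hit_counts
    data.frame(label = lb, gene = names(hc), hit_count = unname(hc),
               sqrt_hit_count = sqrt(unname(hc)), stringsAsFactors = FALSE)
  }))
  tab$label <- factor(tab$label, levels = names(censuses))
  tab$gene <- factor(tab$gene, levels = unique(tab$gene))
  bar <- ggplot2::ggplot(tab, ggplot2::aes(x = .data$gene,
                                           y = .data$sqrt_hit_count)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~label, ncol = 1) +
    ggplot2::labs(x = NULL, y = "sqrt(hits per single-copy gene)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       size = 4, hjust = 1))
  box <- ggplot2::ggplot(tab, ggplot2::aes(x = .data$label,
                                           y = .data$hit_count)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = "hits per single-copy gene") +
    ggplot2::theme_minimal()
  list(table = tab, bar_plot = bar, box_plot = box)
}

#' Write a census report TSV
#'
#' One row per gene with its hit count; header comment lines record the
#' e-value cutoff and the genome-count estimate.
#'
#' @param census_obj An `scg_census`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_census <- function(census_obj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# evalue_max: ", format(census_obj$evalue_max)),
    paste0("# estimated_bacterial_genomes: ", census_obj$estimated_genomes,
           " (multimodal: ", tolower(census_obj$multimodal), ")"),
    "gene\thit_count"), con)
  writeLines(paste(names(census_obj$hit_counts), census_obj$hit_counts,
                   sep = "\t"), con)
  invisible(path)
}
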