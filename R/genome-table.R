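# Canonical columns of the NCBI "datasets" genome summary dialect, keyed by
# the internal field name.  Header matching is case-insensitive and tolerant
# of the snake_case variants produced by newer exports.
.genome_columns <- c(
  assembly_name = "Assembly Name",
  organism_name = "Organism Name",
  size_bp       = "Assembly Stats Total Sequence Length",
  total_genes   = "Annotation Count Gene Total",
  pc_genes      = "Annotation Count Gene Protein-coding",
  ps_genes      = "Annotation Count Gene Pseudogene"
)

.domains <- c("Bacteria", "Archaea", "Eukaryota", "unknown")

# Normalize a header name: lowercase, runs of non-alphanumerics -> "_".
.norm_header <- function(x) {
  x <- tolower(trimws(x))
  x <- gsub("[^a-z0-9]+", "_", x)
  gsub("^_|_$", "", x)
}

#' Construct a validated set of genome records
#'
#' A genome record holds the per-genome annotation summary used throughout
#' the package: total, protein-coding and pseudogene counts, total sequence
#' length, and an optional domain label. The non-coding gene count is always
#' derived as \code{total_genes - pc_genes - ps_genes}; it is never supplied.
#'
#' @param assembly_name,organism_name character identifiers.
#' @param total_genes,pc_genes,ps_genes non-negative integer gene counts.
#' @param size_bp positive integer total sequence length in base pairs.
#' @param domain optional label, one of \code{"Bacteria"}, \code{"Archaea"},
#'   \code{"Eukaryota"} or \code{"unknown"}.
#'
#' @return A data frame of class \code{"genome_records"} with the derived
#'   \code{nc_genes} column.
#' @examples
#' genome_records("asm1", "Escherichia coli", 4500, 4200, 150, 4.6e6,
#'                domain = "Bacteria")
#' @export
genome_records <- function(assembly_name, organism_name, total_genes,
                           pc_genes, ps_genes, size_bp, domain = "unknown") {
  n <- length(total_genes)
  domain <- rep_len(as.character(domain), n)
  rec <- data.frame(
    assembly_name = as.character(assembly_name),
    organism_name = as.character(organism_name),
    total_genes = as.integer(round(total_genes)),
    pc_genes = as.integer(round(pc_genes)),
    ps_genes = as.integer(round(ps_genes)),
    size_bp = as.numeric(size_bp),
    domain = ifelse(domain %in% .domains, domain, "unknown"),
    stringsAsFactors = FALSE
  )
  rec$nc_genes <- rec$total_genes - rec$pc_genes - rec$ps_genes
  bad <- .invalid_reason(rec)
  if (any(!is.na(bad)))
    stop("invalid genome record(s): ", bad[!is.na(bad)][1L])
  class(rec) <- c("genome_records", "data.frame")
  rec
}

# Per-row validity check; returns NA for valid rows, a reason otherwise.
.invalid_reason <- function(rec) {
  reason <- rep(NA_character_, nrow(rec))
  num <- c("total_genes", "pc_genes", "ps_genes", "size_bp")
  miss <- Reduce(`|`, lapply(rec[num], function(x) !is.finite(x)))
  reason[miss] <- "missing or non-numeric annotation count"
  neg <- !miss & (rec$total_genes < 0 | rec$pc_genes < 0 | rec$ps_genes < 0)
  reason[neg] <- "negative gene count"
  tiny <- !miss & rec$size_bp < 1
  reason[tiny] <- "sequence length below 1 bp"
  over <- !miss & (rec$pc_genes + rec$ps_genes > rec$total_genes)
  reason[over] <- "protein-coding + pseudogene counts exceed total genes"
  reason
}

#' Read a genome summary table
#'
#' Reads a tab-separated genome summary in the NCBI \code{datasets} dialect
#' (one header row; columns \dQuote{Assembly Name}, \dQuote{Organism Name},
#' \dQuote{Assembly Stats Total Sequence Length}, \dQuote{Annotation Count
#' Gene Total}, \dQuote{Annotation Count Gene Protein-coding},
#' \dQuote{Annotation Count Gene Pseudogene}, optional \dQuote{Domain}).
#' Header matching is case-insensitive and accepts snake_case aliases.
#' Non-coding counts are derived by subtracting protein-coding genes and
#' pseudogenes from the total.
#'
#' @param path path to a tab-separated file.
#' @param strict if \code{TRUE}, any invalid row (missing counts, or
#'   \code{pc + ps > total}) aborts; by default invalid rows are dropped and
#'   reported in the \code{"dropped"} attribute of the result.
#'
#' @return A \code{genome_records} data frame. In lenient mode the attribute
#'   \code{"dropped"} holds a data frame with the line number and reason for
#'   every discarded row.
#' @seealso [write_genome_table()]
#' @export
read_genome_table <- function(path, strict = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, check.names = FALSE, quote = "",
                           comment.char = "", stringsAsFactors = FALSE,
                           colClasses = "character")
  have <- .norm_header(names(raw))
  want <- .norm_header(.genome_columns)
  idx <- match(want, have)
  if (anyNA(idx)) {
    missing_col <- .genome_columns[is.na(idx)][1L]
    stop("genome table format error: missing mandatory column \"",
         missing_col, "\"")
  }
  num <- function(x) suppressWarnings(as.numeric(x))
  rec <- data.frame(
    assembly_name = raw[[idx[1L]]],
    organism_name = raw[[idx[2L]]],
    total_genes = num(raw[[idx[4L]]]),
    pc_genes = num(raw[[idx[5L]]]),
    ps_genes = num(raw[[idx[6L]]]),
    size_bp = num(raw[[idx[3L]]]),
    stringsAsFactors = FALSE
  )
  dom_idx <- match("domain", have)
  rec$domain <- if (is.na(dom_idx)) "unknown" else raw[[dom_idx]]
  rec$domain[!(rec$domain %in% .domains)] <- "unknown"
  rec$nc_genes <- rec$total_genes - rec$pc_genes - rec$ps_genes

  reason <- .invalid_reason(rec)
  if (strict && any(!is.na(reason))) {
    i <- which(!is.na(reason))[1L]
    stop("invalid genome record at data row ", i, ": ", reason[i])
  }
  keep <- is.na(reason)
  dropped <- data.frame(row = which(!keep), reason = reason[!keep],
                        stringsAsFactors = FALSE)
  rec <- rec[keep, , drop = FALSE]
  rownames(rec) <- NULL
  ints <- c("total_genes", "pc_genes", "ps_genes", "nc_genes")
  rec[ints] <- lapply(rec[ints], as.integer)
  class(rec) <- c("genome_records", "data.frame")
  attr(rec, "dropped") <- dropped
  rec
}

#' Write a genome summary table
#'
#' Writes records in the same tab-separated dialect accepted by
#' [read_genome_table()], so that a read of the written file reproduces all
#' fields exactly. The derived non-coding count is not written; it is
#' re-derived on read.
#'
#' @param records a \code{genome_records} data frame.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
write_genome_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  out <- data.frame(
    records$assembly_name, records$organism_name,
    format(records$size_bp, scientific = FALSE, trim = TRUE),
    records$total_genes, records$pc_genes, records$ps_genes,
    records$domain,
    stringsAsFactors = FALSE, check.names = FALSE
  )
  names(out) <- c(.genome_columns[c("assembly_name", "organism_name",
                                    "size_bp", "total_genes",
                                    "pc_genes", "ps_genes")], "Domain")
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write genome table to ", path, ": ",
                        conditionMessage(ok))
  invisible(path)
}

#' @export
print.genome_records <- function(x, ...) {
  cat(sprintf("Genome records: %d genomes\n", nrow(x)))
  dropped <- attr(x, "dropped")
  if (!is.null(dropped) && nrow(dropped) > 0L)
    cat(sprintf("  (%d invalid rows dropped on read)\n", nrow(dropped)))
  NextMethod()
}
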