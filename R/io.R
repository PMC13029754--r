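#' Read a gene-level count matrix
#'
#' Two plain-text dialects are accepted. `"tsv"` is a dense table whose
#' first column holds gene ids and whose header names the samples;
#' `"triplet"` is a sparse long format with one `gene_id<TAB>sample_id<TAB>count`
#' record per line (comment lines starting with `%` are ignored; an optional
#' leading all-numeric line declaring `n_genes n_samples n_records` is
#' checked against the records). Pairs absent from a triplet file are zero.
#' Identifiers are case-sensitive and taken verbatim.
#'
#' @param path Path to the file.
#' @param dialect `"tsv"` (dense, default) or `"triplet"` (sparse).
#' @param partner Partner the matrix belongs to, `"host"` or `"symbiont"`.
#' @return A [count_matrix()].
#' @seealso [write_counts()]
#' @export
read_counts <- function(path, dialect = c("tsv", "triplet"),
                        partner = c("host", "symbiont")) {
  dialect <- match.arg(dialect)
  partner <- match.arg(partner)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "tsv") read_counts_tsv(path, partner) else read_counts_triplet(path, partner)
}

read_counts_tsv <- function(path, partner) {
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (length(header) < 3L) {
    stop("malformed header at line 1 of ", path,
         ": expected gene_id plus >= 2 sample columns", call. = FALSE)
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = c("character", rep("numeric", length(header) - 1L)),
                          quote = "")
  genes <- df[[1L]]
  if (anyDuplicated(genes)) {
    dup <- unique(genes[duplicated(genes)])
    stop("duplicate gene id(s) in ", path, ": ",
         paste(utils::head(dup, 5), collapse = ", "), call. = FALSE)
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- genes
  count_matrix(m, partner)
}

read_counts_triplet <- function(path, partner) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*%", lines) & nzchar(trimws(lines))]
  if (!length(lines)) stop("empty triplet file: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 3L)
  if (length(bad)) {
    stop("parse error in ", path, ": line ", bad[1L],
         " does not have 3 tab-separated fields", call. = FALSE)
  }
  first <- fields[[1L]]
  dims <- suppressWarnings(as.numeric(first))
  declared <- NULL
  if (!anyNA(dims)) {           # all-numeric first line = declared dimensions
    declared <- dims
    fields <- fields[-1L]
    if (!length(fields)) stop("triplet file declares dimensions but has no records",
                              call. = FALSE)
  }
  rec <- do.call(rbind, fields)
  gene <- rec[, 1L]
  sample <- rec[, 2L]
  val <- suppressWarnings(as.numeric(rec[, 3L]))
  if (anyNA(val)) {
    stop("parse error in ", path, ": non-numeric count value", call. = FALSE)
  }
  if (!is.null(declared) && length(declared) >= 3L && declared[3L] != nrow(rec)) {
    stop("triplet file declares ", declared[3L], " records but has ", nrow(rec),
         call. = FALSE)
  }
  genes <- unique(gene)
  samples <- unique(sample)
  key <- paste(gene, sample, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (gene, sample) record in ", path, call. = FALSE)
  }
  m <- matrix(0, nrow = length(genes), ncol = length(samples),
              dimnames = list(genes, samples))
  m[cbind(match(gene, genes), match(sample, samples))] <- val
  count_matrix(m, partner)
}

#' Write a count matrix as a dense tab-separated table
#'
#' Inverse of [read_counts()] for the `"tsv"` dialect: integer counts
#' round-trip bit-exactly.
#'
#' @param x A [count_matrix()] (or integer matrix with dimnames).
#' @param path Output path.
#' @export
write_counts <- function(x, path) {
  df <- data.frame(gene_id = rownames(x), unclass(x),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata for a dual-library experiment
#'
#' Expects fixed tab-separated columns `sample_id`, `treatment` (WE2 or
#' WWL2), `replicate`, `total_clean_reads`, `host_mapped`,
#' `symbiont_mapped`. Read accounting is validated: partner-mapped reads
#' may not exceed the sample's total clean reads.
#'
#' @param path Path to the metadata tsv.
#' @return A data frame with the columns above, treatments as factor
#'   with levels `WE2`, `WWL2`.
#' @export
read_sample_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "")
  validate_sample_table(df)
}

#' @rdname read_sample_table
#' @param samples A sample-table data frame to validate (and normalize).
#' @export
validate_sample_table <- function(samples) {
  need <- c("sample_id", "treatment", "replicate", "total_clean_reads",
            "host_mapped", "symbiont_mapped")
  miss <- setdiff(need, names(samples))
  if (length(miss)) {
    stop("sample table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample_id", call. = FALSE)
  if (!all(samples$treatment %in% c("WE2", "WWL2"))) {
    stop("treatment must be WE2 or WWL2", call. = FALSE)
  }
  samples$treatment <- factor(samples$treatment, levels = c("WE2", "WWL2"))
  if (any(samples$replicate < 1 | samples$replicate != round(samples$replicate))) {
    stop("replicate must be a positive integer", call. = FALSE)
  }
  over <- samples$host_mapped > samples$total_clean_reads |
    samples$symbiont_mapped > samples$total_clean_reads |
    samples$host_mapped + samples$symbiont_mapped > samples$total_clean_reads
  if (any(over)) {
    stop("partner-mapped reads exceed total clean reads for sample(s): ",
         paste(samples$sample_id[over], collapse = ", "), call. = FALSE)
  }
  samples
}

#' @rdname read_sample_table
#' @export
write_sample_table <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene-set (module) definitions in GMT format
#'
#' One set per line: `name<TAB>description<TAB>gene1<TAB>gene2...`.
#' Duplicated genes within a line are dropped with a warning (sets have
#' set semantics); duplicated set names across lines are an error.
#'
#' @param path Path to a GMT file.
#' @param partner Optional partner tag (`"host"`/`"symbiont"`) applied to
#'   all modules in the file.
#' @return A named list of modules, each a list with elements
#'   `module_id`, `description`, `partner`, `gene_ids`.
#' @export
read_gene_sets <- function(path, partner = NA_character_) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad)) {
    stop("parse error in ", path, ": line ", bad[1L],
         " has fewer than 3 tab-separated fields", call. = FALSE)
  }
  mods <- lapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    genes <- f[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (!length(genes)) stop("empty gene set '", f[1L], "' at line ", i, call. = FALSE)
    if (anyDuplicated(genes)) {
      warning("duplicated gene(s) in set '", f[1L], "' de-duplicated", call. = FALSE)
      genes <- unique(genes)
    }
    module_definition(f[1L], genes, partner = partner, description = f[2L])
  })
  ids <- vapply(mods, `[[`, "", "module_id")
  if (anyDuplicated(ids)) {
    stop("duplicate gene-set name(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  names(mods) <- ids
  mods
}

#' Construct a module (gene set) definition
#'
#' @param module_id Set name, unique within a catalog.
#' @param gene_ids Character vector of member gene ids (de-duplicated).
#' @param partner Optional partner tag.
#' @param description Free-text description (stored, otherwise unused).
#' @export
module_definition <- function(module_id, gene_ids, partner = NA_character_,
                              description = "") {
  stopifnot(is.character(module_id), length(module_id) == 1L, nzchar(module_id))
  gene_ids <- unique(as.character(gene_ids))
  if (!length(gene_ids)) stop("module '", module_id, "' has no genes", call. = FALSE)
  list(module_id = module_id, description = description,
       partner = partner, gene_ids = gene_ids)
}

#' @rdname read_gene_sets
#' @param modules List of module definitions to write.
#' @export
write_gene_sets <- function(modules, path) {
  lines <- vapply(modules, function(m) {
    paste(c(m$module_id,
            if (nzchar(m$description)) m$description else "na",
            m$gene_ids), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Partner-mapped read rate of a mixed-RNA library
#'
#' In nodule dual RNA-seq the library is dominated by host transcripts, so
#' the informative symbiont-side quantity is the fraction of *total clean
#' reads* that map to the symbiont genome: `100 * mapped / total`. This is
#' not comparable with a single-species mapping rate.
#'
#' @param mapped Partner-mapped read count(s).
#' @param total Total clean read count(s), > 0.
#' @return Percentage(s) in `[0, 100]`.
#' @examples
#' mapped_rate(5, 100)   # 5
#' @export
mapped_rate <- function(mapped, total) {
  if (any(total <= 0)) stop("mapped rate undefined: total clean reads must be > 0",
                            call. = FALSE)
  if (any(mapped < 0)) stop("mapped reads must be >= 0", call. = FALSE)
  if (any(mapped > total)) stop("mapped reads exceed total clean reads", call. = FALSE)
  100 * mapped / total
}
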