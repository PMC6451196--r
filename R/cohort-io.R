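#' Write a cohort to a directory of plain-text files
#'
#' Emits `phenotypes.tsv`, `connectivity.tsv` (dense, one row per subject,
#' `edge_<k>` columns), `edges.tsv` (edge id to region-pair map),
#' `genotypes.tsv` (or a minimal GT-only VCF) and `truth.json`. Numeric
#' values are written with shortest round-trip precision so the files read
#' back losslessly.
#'
#' @param cohort a `bt_cohort` object.
#' @param dir output directory (created if absent).
#' @param genotype_format `"tsv"` (default) or `"vcf"` (minimal, GT-only;
#'   a TSV is always written so the cohort round-trips).
#' @return invisibly, the vector of files written.
#' @export
write_cohort <- function(cohort, dir, genotype_format = c("tsv", "vcf")) {
  genotype_format <- match.arg(genotype_format)
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok) stop("cannot create directory: ", dir, call. = FALSE)
  paths <- file.path(dir, c("phenotypes.tsv", "connectivity.tsv", "edges.tsv",
                            "genotypes.tsv", "truth.json"))
  names(paths) <- c("phenotypes", "connectivity", "edges", "genotypes",
                    "truth")
  tsv <- function(x, path) {
    x <- as.data.frame(x)
    # doubles via %.17g so values parse back bit-identically
    dbl <- vapply(x, is.double, logical(1))
    x[dbl] <- lapply(x[dbl], function(col) sprintf("%.17g", col))
    data.table::fwrite(x, path, sep = "\t", quote = FALSE)
  }
  tryCatch({
    tsv(cohort$phenotypes, paths["phenotypes"])
    conn <- data.frame(subject_id = rownames(cohort$connectivity) %||%
                         character(0), check.names = FALSE)
    conn <- cbind(conn, as.data.frame(cohort$connectivity))
    tsv(conn, paths["connectivity"])
    tsv(cohort$edges, paths["edges"])
    geno <- data.frame(subject_id = rownames(cohort$genotypes) %||%
                         character(0), check.names = FALSE)
    geno <- cbind(geno, as.data.frame(cohort$genotypes))
    tsv(geno, paths["genotypes"])
    jsonlite::write_json(cohort$truth, paths["truth"], auto_unbox = TRUE,
                         digits = I(17), dataframe = "columns")
    if (genotype_format == "vcf") {
      write_minimal_vcf(cohort$genotypes, file.path(dir, "genotypes.vcf"))
      paths <- c(paths, vcf = file.path(dir, "genotypes.vcf"))
    }
  }, error = function(e) {
    stop("failed writing cohort under ", dir, ": ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(paths)
}

# Minimal VCF 4.2 writer: one pseudo-locus per SNP column, GT-only FORMAT,
# binary carrier coding 0/0 vs 0/1.
write_minimal_vcf <- function(genotypes, path) {
  ids <- rownames(genotypes) %||% paste0("S", seq_len(nrow(genotypes)))
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", ids), collapse = "\t"))
  gt <- ifelse(t(genotypes) == 1, "0/1", "0/0")
  body <- paste("1", seq_len(ncol(genotypes)),
                colnames(genotypes) %||% paste0("snp_", seq_len(ncol(genotypes))),
                "A", "G", ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  if (ncol(genotypes) == 0) body <- character(0)
  writeLines(c(header, body), path)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing the cohort files.
#' @return a `bt_cohort` object (the generator `config` is not persisted and
#'   comes back NULL; all data components round-trip exactly).
#' @export
read_cohort <- function(dir) {
  need <- file.path(dir, c("phenotypes.tsv", "connectivity.tsv", "edges.tsv",
                           "genotypes.tsv", "truth.json"))
  missing <- need[!file.exists(need)]
  if (length(missing)) {
    stop("missing cohort file(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  pheno <- as.data.frame(data.table::fread(need[1], sep = "\t"))
  conn_df <- as.data.frame(data.table::fread(need[2], sep = "\t"))
  edges <- as.data.frame(data.table::fread(need[3], sep = "\t"))
  geno_df <- as.data.frame(data.table::fread(need[4], sep = "\t"))
  to_matrix <- function(df, mode) {
    m <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(m) <- mode
    rownames(m) <- df$subject_id
    m
  }
  truth <- jsonlite::read_json(need[5], simplifyVector = TRUE)
  structure(list(phenotypes = pheno,
                 connectivity = to_matrix(conn_df, "double"),
                 edges = edges, genotypes = to_matrix(geno_df, "integer"),
                 truth = truth, config = NULL),
            class = "bt_cohort")
}
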