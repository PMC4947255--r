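## Readers/writers for the plain-text dialects the pipeline exchanges:
## matrices as TSV with a probe_id first column, sample sheet as CSV,
## kinship as a square TSV, genotypes as 0/1/2 TSV or minimal VCF.

matrix_to_dt <- function(x) {
  dt <- data.table::as.data.table(x, keep.rownames = "probe_id")
  dt
}

dt_to_matrix <- function(dt, id_col = "probe_id") {
  if (is.numeric(id_col)) id_col <- names(dt)[id_col]
  ids <- as.character(dt[[id_col]])
  m <- as.matrix(dt[, setdiff(names(dt), id_col), with = FALSE])
  rownames(m) <- ids
  storage.mode(m) <- "double"
  m
}

#' Write a methyl_dataset to a directory of plain-text files
#'
#' Matrices go to TSV (first column `probe_id`), the sample sheet to CSV and
#' the provenance trail to a one-label-per-line text file. The layout is the
#' same one [load_dataset()] reads, and a write/load round trip is lossless
#' to at least 10 significant digits.
#'
#' @param ds A [methyl_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(x, file) {
    if (is.null(x)) return(invisible())
    data.table::fwrite(matrix_to_dt(x), file.path(dir, file), sep = "\t")
  }
  wr(ds$meth, "meth.tsv")
  wr(ds$unmeth, "unmeth.tsv")
  wr(ds$beta, "beta.tsv")
  wr(ds$detection_p, "detection_p.tsv")
  wr(ds$bead_count, "bead_count.tsv")
  wr(ds$oob_meth, "oob_meth.tsv")
  wr(ds$oob_unmeth, "oob_unmeth.tsv")
  if (!is.null(ds$controls)) {
    data.table::fwrite(ds$controls, file.path(dir, "controls.tsv"), sep = "\t")
  }
  data.table::fwrite(ds$annotation, file.path(dir, "annotation.tsv"), sep = "\t")
  data.table::fwrite(ds$samples, file.path(dir, "samples.csv"))
  writeLines(ds$provenance, file.path(dir, "provenance.txt"))
  invisible(dir)
}

#' Load a methyl_dataset from a directory written by write_dataset
#'
#' At minimum `annotation.tsv`, `samples.csv` and either `beta.tsv` or both
#' intensity files must be present; all other matrices are optional.
#' Mismatched probe or sample ids are rejected, naming the first offenders.
#'
#' @param dir Directory containing the files.
#' @return A [methyl_dataset()].
#' @export
load_dataset <- function(dir) {
  rd <- function(file) {
    path <- file.path(dir, file)
    if (!file.exists(path)) return(NULL)
    dt_to_matrix(data.table::fread(path, sep = "\t"))
  }
  ann_path <- file.path(dir, "annotation.tsv")
  smp_path <- file.path(dir, "samples.csv")
  if (!file.exists(ann_path)) stop("missing annotation.tsv in ", dir)
  if (!file.exists(smp_path)) stop("missing samples.csv in ", dir)
  annotation <- tibble::as_tibble(data.table::fread(ann_path, sep = "\t"))
  annotation$probe_id <- as.character(annotation$probe_id)
  annotation$is_idmr <- as.logical(annotation$is_idmr)
  samples <- tibble::as_tibble(data.table::fread(smp_path))
  samples$sample_id <- as.character(samples$sample_id)
  if (is.logical(samples$replicate_group)) {
    samples$replicate_group <- as.character(samples$replicate_group)
  }
  samples$replicate_group[!is.na(samples$replicate_group) &
                            samples$replicate_group == ""] <- NA_character_
  controls <- NULL
  if (file.exists(file.path(dir, "controls.tsv"))) {
    controls <- tibble::as_tibble(
      data.table::fread(file.path(dir, "controls.tsv"), sep = "\t"))
  }
  prov <- character()
  if (file.exists(file.path(dir, "provenance.txt"))) {
    prov <- readLines(file.path(dir, "provenance.txt"))
  }
  bead <- rd("bead_count.tsv")
  if (!is.null(bead)) storage.mode(bead) <- "integer"
  methyl_dataset(
    meth = rd("meth.tsv"), unmeth = rd("unmeth.tsv"), beta = rd("beta.tsv"),
    annotation = annotation, samples = samples,
    detection_p = rd("detection_p.tsv"), bead_count = bead,
    oob_meth = rd("oob_meth.tsv"), oob_unmeth = rd("oob_unmeth.tsv"),
    controls = controls, provenance = prov
  )
}

#' Read a kinship matrix from a square TSV
#'
#' Expects sample ids both as the header and the first column; the matrix
#' must be symmetric with entries in `[0, 1]`.
#'
#' @param path TSV file path.
#' @return Symmetric numeric matrix with sample-id dimnames.
#' @export
read_kinship <- function(path) {
  k <- dt_to_matrix(data.table::fread(path, sep = "\t"), id_col = 1L)
  if (!isTRUE(all.equal(k, t(k), tolerance = 1e-8))) {
    stop("kinship matrix is not symmetric")
  }
  if (min(k) < 0 || max(k) > 1) stop("kinship entries must lie in [0, 1]")
  k
}

#' Write a kinship matrix as a square TSV
#' @param k Symmetric matrix with sample-id dimnames.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_kinship <- function(k, path) {
  dt <- data.table::as.data.table(k, keep.rownames = "sample_id")
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read genotypes as a SNPs x samples dosage matrix
#'
#' Accepts either a TSV of 0/1/2 dosages (first columns `snp_id`,
#' `chromosome`, `position`, then one column per sample) or a VCF with
#' diploid `GT` fields, from which additive dosages are derived.
#'
#' @param path File path (`.vcf` or TSV).
#' @return List with `g` (SNPs x samples integer matrix, `NA` for missing)
#'   and `positions` (tibble: `snp_id`, `chromosome`, `position`).
#' @export
read_genotypes <- function(path) {
  if (grepl("\\.vcf$", path, ignore.case = TRUE)) {
    return(read_genotypes_vcf(path))
  }
  dt <- data.table::fread(path, sep = "\t")
  meta <- c("snp_id", "chromosome", "position")
  if (!all(meta %in% names(dt))) {
    stop("genotype TSV must have columns snp_id, chromosome, position")
  }
  g <- as.matrix(dt[, setdiff(names(dt), meta), with = FALSE])
  rownames(g) <- as.character(dt$snp_id)
  storage.mode(g) <- "integer"
  if (any(!is.na(g) & !(g %in% 0:2))) stop("dosages must be 0, 1, 2 or NA")
  list(g = g,
       positions = tibble::tibble(snp_id = as.character(dt$snp_id),
                                  chromosome = as.character(dt$chromosome),
                                  position = dt$position))
}

read_genotypes_vcf <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "##")]
  header <- strsplit(sub("^#", "", lines[1]), "\t")[[1]]
  body <- lines[-1]
  if (!length(body)) stop("VCF contains no variant records")
  fields <- strsplit(body, "\t")
  samples <- header[-(1:9)]
  gt_dose <- function(gt) {
    gt <- sub(":.*$", "", gt)
    if (gt %in% c(".", "./.", ".|.")) return(NA_integer_)
    sum(as.integer(strsplit(gt, "[/|]")[[1]]) > 0)
  }
  g <- t(vapply(fields, function(f) {
    vapply(f[-(1:9)], gt_dose, integer(1))
  }, integer(length(samples))))
  snp_id <- vapply(fields, function(f) {
    if (f[3] == ".") paste0(f[1], ":", f[2]) else f[3]
  }, character(1))
  dimnames(g) <- list(snp_id, samples)
  list(g = g,
       positions = tibble::tibble(
         snp_id = snp_id,
         chromosome = vapply(fields, `[`, character(1), 1),
         position = as.integer(vapply(fields, `[`, character(1), 2))))
}

#' Write genotypes to the 0/1/2 TSV dialect
#' @param geno List as returned by [read_genotypes()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(geno, path) {
  dt <- data.table::data.table(
    snp_id = geno$positions$snp_id,
    chromosome = geno$positions$chromosome,
    position = geno$positions$position)
  dt <- cbind(dt, data.table::as.data.table(geno$g))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}
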