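# Readers and writers for the pipeline's delimited formats. All files are
# tab-separated with a header line, "." as decimal point, and deterministic
# row/column order; every excluded or rejected row is an error naming the
# offending row, never a silent drop.

plate_roles <- function() c("test", "negative_control", "empty")

#' Construct and validate a screen dataset
#'
#' @param platemap Data frame: plate_id, well, role, gene_id, control_type.
#' @param measurements Data frame: plate_id, well, replicate, rlu.
#' @param plate_rows,plate_cols Plate format used for address validation.
#' @return A `screen_dataset` (list of the two validated tables).
#' @export
new_screen_dataset <- function(platemap, measurements,
                               plate_rows = 16L, plate_cols = 24L) {
  need_pm <- c("plate_id", "well", "role", "gene_id", "control_type")
  need_ms <- c("plate_id", "well", "replicate", "rlu")
  if (!all(need_pm %in% names(platemap))) {
    stop_validation("platemap must have columns ", paste(need_pm, collapse = ", "))
  }
  if (!all(need_ms %in% names(measurements))) {
    stop_validation("measurements must have columns ", paste(need_ms, collapse = ", "))
  }
  platemap <- platemap[need_pm]
  measurements <- measurements[need_ms]

  bad <- which(!is_valid_well(platemap$well, plate_rows, plate_cols))
  if (length(bad)) {
    stop_validation("platemap row ", bad[1], ": invalid well address '",
                    platemap$well[bad[1]], "'")
  }
  bad <- which(!platemap$role %in% plate_roles())
  if (length(bad)) {
    stop_validation("platemap row ", bad[1], ": unknown role '",
                    platemap$role[bad[1]], "'")
  }
  key <- paste(platemap$plate_id, platemap$well)
  if (anyDuplicated(key)) {
    stop_validation("platemap row ", which(duplicated(key))[1],
                    ": duplicate well '", key[which(duplicated(key))[1]], "'")
  }
  bad <- which(platemap$role == "test" & (is.na(platemap$gene_id) | platemap$gene_id == ""))
  if (length(bad)) {
    stop_validation("platemap row ", bad[1], ": test well without gene_id")
  }
  genes <- platemap$gene_id[platemap$role == "test"]
  if (anyDuplicated(genes)) {
    stop_validation("gene '", genes[which(duplicated(genes))[1]],
                    "' mapped to more than one test well")
  }

  measurements$replicate <- as.integer(measurements$replicate)
  measurements$rlu <- as.numeric(measurements$rlu)
  bad <- which(is.na(measurements$rlu) | measurements$rlu <= 0)
  if (length(bad)) {
    stop_validation("measurements row ", bad[1], ": nonpositive or missing RLU")
  }
  reps <- sort(unique(measurements$replicate))
  if (length(reps) && !identical(reps, seq_len(length(reps)))) {
    stop_validation("replicate ids must form a contiguous set 1..R, got ",
                    paste(reps, collapse = ","))
  }
  mkey <- paste(measurements$plate_id, measurements$well)
  unmapped <- which(!mkey %in% key)
  if (length(unmapped)) {
    stop_validation("measurements row ", unmapped[1], ": well '",
                    mkey[unmapped[1]], "' not in plate map")
  }
  mrep <- paste(mkey, measurements$replicate)
  if (anyDuplicated(mrep)) {
    stop_validation("measurements row ", which(duplicated(mrep))[1],
                    ": duplicate (plate, well, replicate)")
  }
  role <- platemap$role[match(mkey, key)]
  bad <- which(role == "empty")
  if (length(bad)) {
    stop_validation("measurements row ", bad[1], ": measurement on empty well")
  }
  structure(list(platemap = platemap, measurements = measurements,
                 plate_rows = plate_rows, plate_cols = plate_cols),
            class = "screen_dataset")
}

#' @export
print.screen_dataset <- function(x, ...) {
  cat(sprintf("screen_dataset: %d plates, %d replicates, %d test wells, %d control wells\n",
              length(unique(x$platemap$plate_id)),
              length(unique(x$measurements$replicate)),
              sum(x$platemap$role == "test"),
              sum(x$platemap$role == "negative_control")))
  invisible(x)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
}

read_tsv <- function(path, ...) {
  if (!file.exists(path)) stop_validation("file not found: ", path)
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    na.strings = "", check.names = FALSE, quote = "",
                    comment.char = "", ...)
}

#' Write a screen dataset as a plate-map / measurements file pair
#'
#' @param screen A `screen_dataset`.
#' @param platemap_path,measurements_path Output TSV paths.
#' @return Invisibly, the two paths.
#' @export
write_screen <- function(screen, platemap_path, measurements_path) {
  if (!inherits(screen, "screen_dataset")) {
    stop_validation("screen must be a screen_dataset")
  }
  pm <- screen$platemap[order(screen$platemap$plate_id, screen$platemap$well), ]
  ms <- screen$measurements[order(screen$measurements$replicate,
                                  screen$measurements$plate_id,
                                  screen$measurements$well), ]
  write_tsv(pm, platemap_path)
  write_tsv(ms, measurements_path)
  invisible(c(platemap_path, measurements_path))
}

#' Read and cross-validate a screen from its TSV file pair
#'
#' @inheritParams write_screen
#' @param plate_rows,plate_cols Expected plate format.
#' @return A validated `screen_dataset`.
#' @export
read_screen <- function(platemap_path, measurements_path,
                        plate_rows = 16L, plate_cols = 24L) {
  pm <- read_tsv(platemap_path, colClasses = "character")
  ms <- read_tsv(measurements_path)
  new_screen_dataset(pm, ms, plate_rows, plate_cols)
}

#' Read a gene-by-sample count table
#'
#' First column is the gene identifier; remaining columns are nonnegative
#' integer read counts per sample.
#'
#' @param path TSV path.
#' @return Data frame with a `gene_id` column followed by sample columns.
#' @export
read_counts <- function(path) {
  df <- read_tsv(path)
  if (ncol(df) < 2) stop_validation("count table needs gene_id + >=1 sample column")
  names(df)[1] <- "gene_id"
  if (anyDuplicated(df$gene_id)) {
    stop_validation("duplicate gene_id in count table: ",
                    df$gene_id[which(duplicated(df$gene_id))[1]])
  }
  for (j in 2:ncol(df)) {
    v <- df[[j]]
    if (!is.numeric(v) || anyNA(v) || any(v < 0) || any(v != round(v))) {
      bad <- which(!is.finite(v) | v < 0 | v != round(v))[1]
      stop_validation("count table row ", bad, ", column '", names(df)[j],
                      "': counts must be nonnegative integers")
    }
    df[[j]] <- as.integer(v)
  }
  df
}

#' Write a count table
#' @param counts Data frame from [read_counts()] / [simulate_counts()].
#' @param path Output TSV path.
#' @export
write_counts <- function(counts, path) {
  write_tsv(counts[order(counts$gene_id), ], path)
  invisible(path)
}

#' Read a GMT gene-set library
#'
#' Standard format: one set per line, tab-separated `name`, `description`,
#' then member genes. Lines with fewer than three fields or empty member
#' lists are parse errors naming the line number.
#'
#' @param path GMT path.
#' @return Named list of member vectors with a `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_validation("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop_validation("empty GMT file: ", path)
  lib <- vector("list", length(lines))
  desc <- character(length(lines))
  nm <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) {
      stop_validation("GMT line ", i, ": expected >= 3 tab-separated fields, got ",
                      length(f))
    }
    genes <- f[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (!length(genes)) stop_validation("GMT line ", i, ": empty gene set")
    nm[i] <- f[1]
    desc[i] <- f[2]
    lib[[i]] <- genes
  }
  if (anyDuplicated(nm)) {
    stop_validation("duplicate gene-set name: ", nm[which(duplicated(nm))[1]])
  }
  names(lib) <- nm
  attr(lib, "descriptions") <- stats::setNames(desc, nm)
  lib
}

#' Write a GMT gene-set library
#' @param library Named list of member vectors.
#' @param path Output path.
#' @param descriptions Optional named descriptions (defaults to `"NA"`).
#' @export
write_gmt <- function(library, path, descriptions = NULL) {
  if (!length(library) || is.null(names(library))) {
    stop_validation("library must be a nonempty named list")
  }
  desc <- descriptions[names(library)]
  desc[is.na(desc) | !nzchar(desc)] <- "NA"
  lines <- vapply(seq_along(library), function(i) {
    paste(c(names(library)[i], desc[i], library[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a wide phosphosite table
#' @param path TSV path with site metadata and intensity columns.
#' @return Data frame; logical columns `reverse`/`contaminant` are coerced.
#' @export
read_phospho_table <- function(path) {
  df <- read_tsv(path)
  need <- c("gene", "protein", "position", "residue", "localization_prob",
            "score_diff", "reverse", "contaminant")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop_validation("phosphosite table missing columns: ",
                    paste(miss, collapse = ", "))
  }
  df$reverse <- as.logical(df$reverse)
  df$contaminant <- as.logical(df$contaminant)
  df
}

#' Write result tables plus a JSON run-metadata sidecar
#'
#' @param tables Named list of data frames; each is written as `<name>.tsv`.
#' @param out_dir Output directory, created if needed.
#' @param metadata Named list recorded in `run_metadata.json` alongside the
#'   package version and a deterministic config hash.
#' @return Invisibly, the paths written.
#' @export
write_results <- function(tables, out_dir, metadata = list()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    write_tsv(tables[[nm]], p)
    paths <- c(paths, p)
  }
  meta <- c(metadata, list(
    package = "lumiscreen",
    version = as.character(utils::packageVersion("lumiscreen")),
    config_hash = config_hash(metadata)
  ))
  mp <- file.path(out_dir, "run_metadata.json")
  jsonlite::write_json(meta, mp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(paths, mp))
}
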