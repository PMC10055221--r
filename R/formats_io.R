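#' @importFrom data.table data.table fread fwrite setcolorder setkey as.data.table := .N .SD
NULL

prob_cols <- function() paste0("p_", aa_alphabet())

#' Construct a prediction set
#'
#' A prediction set holds one 20-way probability vector per
#' (protein, position, model) triple, with probabilities indexed in
#' [aa_alphabet()] order. Internally it is a `data.table` with columns
#' `protein_id`, `position`, `model_id`, `p_A` ... `p_Y`.
#'
#' @param protein_id character vector.
#' @param position 1-based integer positions.
#' @param model_id character vector.
#' @param probs numeric matrix, one row per entry, 20 columns in
#'   [aa_alphabet()] order.
#' @return object of class `prediction_set`.
#' @export
prediction_set <- function(protein_id, position, model_id, probs) {
  probs <- matrix(as.numeric(probs), nrow = length(protein_id), ncol = 20L)
  dt <- data.table(protein_id = as.character(protein_id),
                   position = as.integer(position),
                   model_id = as.character(model_id))
  dt[, (prob_cols()) := as.data.table(probs)]
  as_prediction_set(dt)
}

as_prediction_set <- function(dt) {
  data.table::setattr(dt, "class",
                      c("prediction_set", "data.table", "data.frame"))
  dt
}

#' @export
print.prediction_set <- function(x, ...) {
  cat(sprintf("<prediction_set> %d entries, %d protein(s), models: %s\n",
              nrow(x), data.table::uniqueN(x$protein_id),
              paste(pset_models(x), collapse = ", ")))
  invisible(x)
}

#' Model ids present in a prediction set (sorted)
#' @param pset a `prediction_set`.
#' @return character vector.
#' @export
pset_models <- function(pset) sort(unique(pset$model_id))

pset_prob_matrix <- function(pset) {
  as.matrix(pset[, prob_cols(), with = FALSE])
}

#' Read a prediction table
#'
#' Reads the package's tab-separated interchange format for per-site 20-way
#' probability predictions: header `protein_id position model_id p_A ... p_Y`
#' with the 20 probability columns in [aa_alphabet()] order and 1-based
#' positions. Probability vectors whose sum deviates from 1 by at most 1e-3
#' (floating-point serialization slack) are renormalized to sum exactly 1;
#' larger deviations are treated as corrupt rows and rejected. If some
#' (protein, position) pair is present for only a subset of the models in the
#' file, a warning lists the incomplete sites.
#'
#' @param path file path.
#' @return a [prediction_set()].
#' @export
read_prediction_table <- function(path) {
  if (!file.exists(path))
    stop_resstack("resstack_io_error", "file not found: %s", path)
  dt <- fread(path, sep = "\t", header = TRUE)
  expected <- c("protein_id", "position", "model_id", prob_cols())
  missing <- setdiff(expected, names(dt))
  if (length(missing) > 0)
    stop_resstack("resstack_format_error",
                  "prediction table is missing column(s): %s",
                  paste(missing, collapse = ", "))
  dt <- dt[, expected, with = FALSE]
  dt[, `:=`(protein_id = as.character(protein_id),
            model_id = as.character(model_id),
            position = as.integer(position))]
  if (nrow(dt) == 0) return(as_prediction_set(dt))
  dup <- duplicated(dt[, c("protein_id", "position", "model_id")])
  if (any(dup)) {
    d <- dt[which(dup)[1]]
    stop_resstack("resstack_duplicate_error",
                  "duplicate record for (%s, %d, %s)",
                  d$protein_id, d$position, d$model_id)
  }
  p <- as.matrix(dt[, prob_cols(), with = FALSE])
  bad <- which(!is.finite(p) | p < 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop_resstack("resstack_value_error",
                  "non-finite or negative probability in row %d", bad[1, 1])
  s <- rowSums(p)
  off <- which(abs(s - 1) > 1e-3)
  if (length(off) > 0)
    stop_resstack("resstack_value_error",
                  "probabilities in row %d sum to %.6f (outside 1 +/- 1e-3)",
                  off[1], s[off[1]])
  dt[, (prob_cols()) := as.data.table(p / s)]
  pset <- as_prediction_set(dt)
  inc <- incomplete_sites(pset)
  if (nrow(inc) > 0)
    warning(sprintf("%d site(s) missing for some models, e.g. (%s, %d)",
                    nrow(inc), inc$protein_id[1], inc$position[1]),
            call. = FALSE)
  pset
}

# sites not covered by every model in the set
incomplete_sites <- function(pset) {
  n_models <- length(pset_models(pset))
  cov <- pset[, list(n = .N), by = c("protein_id", "position")]
  cov[cov$n < n_models, c("protein_id", "position")]
}

#' Write a prediction table
#'
#' Inverse of [read_prediction_table()]; probabilities survive a write/read
#' round trip to within 1e-9 (values are serialized at full double
#' precision).
#'
#' @param pset a `prediction_set`.
#' @param path output path.
#' @export
write_prediction_table <- function(pset, path) {
  cols <- c("protein_id", "position", "model_id", prob_cols())
  ok <- tryCatch({
    fwrite(pset[, cols, with = FALSE], path, sep = "\t", quote = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop_resstack("resstack_io_error", "cannot write %s: %s", path,
                  conditionMessage(ok))
  invisible(path)
}

#' Read a FASTA file of protein sequences
#'
#' Record ids are the first whitespace-delimited token of each header line;
#' sequences are uppercased and may wrap over any number of lines. Only the
#' 20 canonical amino acids plus `X` (unknown residue) are accepted.
#'
#' @param path file path.
#' @return named character vector, id -> sequence.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path))
    stop_resstack("resstack_io_error", "file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grepl("^>", lines)
  if (length(lines) > 0 && !hdr[1])
    stop_resstack("resstack_format_error", "FASTA does not start with '>'")
  rec <- cumsum(hdr)
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- vapply(strsplit(ids, "\\s+"), `[`, character(1), 1)
  seqs <- vapply(split(lines[!hdr], rec[!hdr]), paste0, character(1),
                 collapse = "")
  out <- character(length(ids))
  names(out) <- ids
  present <- as.integer(names(seqs))
  out[present] <- toupper(gsub("\\s", "", seqs))
  empty <- which(!nzchar(out))
  if (length(empty) > 0)
    stop_resstack("resstack_format_error", "empty FASTA record '%s'",
                  ids[empty[1]])
  ok_letters <- c(aa_alphabet(), "X")
  for (i in seq_along(out)) {
    letters_i <- strsplit(out[[i]], "")[[1]]
    bad <- which(!(letters_i %in% ok_letters))
    if (length(bad) > 0)
      stop_resstack("resstack_format_error",
                    "record '%s': invalid character '%s' at position %d",
                    ids[i], letters_i[bad[1]], bad[1])
  }
  out
}

#' Parse an RCSB-style sequence cluster file
#'
#' Each nonblank line is one homology cluster of whitespace-separated member
#' ids (entity ids such as `1ABC_1`), in the format of RCSB's
#' clusters-by-entity lists. Cluster ordinals follow line order.
#'
#' @param path file path.
#' @return object of class `cluster_table`: list with `clusters` (list of
#'   character vectors) and `member_index` (named integer vector mapping each
#'   member id to its 1-based cluster ordinal).
#' @export
parse_cluster_file <- function(path) {
  if (!file.exists(path))
    stop_resstack("resstack_io_error", "file not found: %s", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  clusters <- strsplit(lines, "\\s+")
  members <- unlist(clusters, use.names = FALSE)
  dup <- members[duplicated(members)]
  if (length(dup) > 0)
    stop_resstack("resstack_consistency_error",
                  "id '%s' appears in more than one cluster", dup[1])
  member_index <- rep.int(seq_along(clusters),
                          vapply(clusters, length, integer(1)))
  names(member_index) <- members
  structure(list(clusters = clusters, member_index = member_index),
            class = "cluster_table")
}

#' @export
print.cluster_table <- function(x, ...) {
  cat(sprintf("<cluster_table> %d clusters, %d members\n",
              length(x$clusters), length(x$member_index)))
  invisible(x)
}

# PDB id vs entity id matching: case-insensitive prefix before the underscore
norm_pdb_id <- function(id) toupper(sub("_.*$", "", id))

# all cluster ordinals containing an id with the given normalized prefix
clusters_of <- function(clusters, norm_id) {
  norm_members <- norm_pdb_id(names(clusters$member_index))
  unique(clusters$member_index[norm_members %in% norm_id])
}

#' Filter training-set candidates
#'
#' Applies the training-set curation rules: a candidate is removed if (a) it,
#' or any member of its homology cluster, is among the excluded ids
#' ("homology"); (b) it is longer than `max_length` residues ("length"); or
#' (c) its protonation preprocessing failed ("protonation"). Each removal
#' carries exactly one reason, checked in that order. Candidates absent from
#' the cluster table are retained (subject to b, c) with a warning. Ids are
#' matched to cluster entity ids case-insensitively by the prefix before the
#' underscore.
#'
#' @param candidates data.frame with columns `id`, `length`,
#'   `protonation_ok`.
#' @param excluded_ids character vector of ids (e.g. the test set and the
#'   individual models' training sets) whose homologs must not be trained on.
#' @param clusters a [parse_cluster_file()] result, or NULL to skip homology
#'   expansion (direct id matches still apply).
#' @param max_length maximum chain length retained (default 1024, the input
#'   limit of sequence models with 1024-token windows).
#' @return list with `retained` (character vector of ids, input order) and
#'   `rejected` (data.frame id/reason).
#' @export
filter_training_entries <- function(candidates, excluded_ids,
                                    clusters = NULL, max_length = 1024L) {
  stopifnot(all(c("id", "length", "protonation_ok") %in% names(candidates)))
  excl_norm <- norm_pdb_id(excluded_ids)
  norm_members <- if (!is.null(clusters))
    norm_pdb_id(names(clusters$member_index)) else character(0)
  unclustered <- character(0)
  reason <- rep(NA_character_, nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    id_n <- norm_pdb_id(candidates$id[i])
    in_excl <- id_n %in% excl_norm
    if (!in_excl && !is.null(clusters)) {
      ords <- clusters$member_index[norm_members %in% id_n]
      if (length(ords) == 0) {
        unclustered <- c(unclustered, candidates$id[i])
      } else {
        mates <- norm_pdb_id(unlist(clusters$clusters[unique(ords)],
                                    use.names = FALSE))
        in_excl <- any(mates %in% excl_norm)
      }
    } else if (!in_excl && is.null(clusters)) {
      unclustered <- c(unclustered, candidates$id[i])
    }
    if (in_excl) reason[i] <- "homology"
    else if (candidates$length[i] > max_length) reason[i] <- "length"
    else if (!isTRUE(candidates$protonation_ok[i])) reason[i] <- "protonation"
  }
  if (length(unclustered) > 0)
    warning(sprintf("%d candidate id(s) not found in cluster table (e.g. %s); retained",
                    length(unclustered), unclustered[1]), call. = FALSE)
  keep <- is.na(reason)
  list(retained = candidates$id[keep],
       rejected = data.frame(id = candidates$id[!keep],
                             reason = reason[!keep],
                             stringsAsFactors = FALSE))
}
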