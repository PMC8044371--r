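#' Validate and normalize DNA sequences
#'
#' Uppercases sequences and enforces the A/C/G/T alphabet. Under
#' `policy = "strict"` any other character is an error naming the offending
#' 1-based position; under `policy = "skip"` the offending records are
#' dropped and counted.
#'
#' @param seqs character vector of raw sequences.
#' @param policy `"strict"` (default) or `"skip"`.
#' @param ids optional record identifiers used in messages.
#' @return A list with `seq` (normalized sequences that passed), `keep`
#'   (logical vector over the input) and `n_dropped`.
#' @export
validate_seqs <- function(seqs, policy = c("strict", "skip"), ids = NULL) {
  policy <- match.arg(policy)
  if (is.null(ids)) ids <- paste0("record ", seq_along(seqs))
  up <- toupper(seqs)
  bad_at <- regexpr("[^ACGT]", up)
  bad <- bad_at > 0L | nchar(up) == 0L
  if (any(bad)) {
    first <- which(bad)[1L]
    what <- if (nchar(up[first]) == 0L) {
      paste0("empty sequence in ", ids[first])
    } else {
      paste0("non-ACGT character '", substr(up[first], bad_at[first], bad_at[first]),
             "' at position ", bad_at[first], " in ", ids[first])
    }
    if (policy == "strict") stop(what, " (policy = \"strict\")")
    message("dropping ", sum(bad), " record(s); first offence: ", what)
  }
  list(seq = up[!bad], keep = !bad, n_dropped = sum(bad))
}

#' Validate a single sequence
#'
#' Scalar convenience over [validate_seqs()]: returns the normalized string,
#' or `NA_character_` when the record is dropped under `policy = "skip"`.
#'
#' @inheritParams validate_seqs
#' @param seq a single sequence string.
#' @export
validate_seq <- function(seq, policy = c("strict", "skip")) {
  policy <- match.arg(policy)
  out <- validate_seqs(seq, policy = policy)
  if (out$n_dropped > 0L) NA_character_ else out$seq
}

#' Read one labeled FASTA file
#'
#' Reads a FASTA file of sequence windows that all share one task and one
#' class label, yielding the labeled-sequence table that is the atom of all
#' pipelines here.
#'
#' @param path FASTA file path.
#' @param task task name, e.g. `"4mC:C.equisetifolia"`.
#' @param label class label, 0 (negative) or 1 (positive site).
#' @param policy alphabet policy, see [validate_seqs()].
#' @return A data.frame with columns `id`, `seq`, `label`, `task`.
#' @export
read_fasta <- function(path, task, label, policy = c("strict", "skip")) {
  policy <- match.arg(policy)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  label <- check_label(label)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  v <- validate_seqs(as.character(set), policy = policy,
                     ids = paste0("record '", ids, "' of ", path))
  data.frame(id = ids[v$keep], seq = v$seq,
             label = rep(label, sum(v$keep)),
             task = rep(task, sum(v$keep)),
             stringsAsFactors = FALSE)
}

#' Write sequences to single-line FASTA
#'
#' @param x a data.frame with columns `id` and `seq`, or a named character
#'   vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  if (is.data.frame(x)) {
    seqs <- stats::setNames(x$seq, x$id)
  } else {
    seqs <- x
  }
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = max(nchar(seqs)) + 1L)
  invisible(path)
}

check_label <- function(label) {
  lab <- suppressWarnings(as.integer(label))
  if (length(lab) != 1L || is.na(lab) || !lab %in% c(0L, 1L)) {
    stop("label must be 0 or 1, got: ", deparse(label))
  }
  lab
}

#' Assemble a multi-task registry from labeled-sequence tables
#'
#' @param records data.frame with columns `id`, `seq`, `label`, `task`,
#'   `split` (`"train"` or `"test"`).
#' @param modification optional named character vector tagging each task as
#'   `"4mC"` or `"6mA"`; by default parsed from a `"<mod>:<species>"` task
#'   name when present.
#' @return An object of class `mt_registry`: `tasks` is an ordered (name
#'   sorted) list, one element per task with `train` and `test`
#'   data.frames; task order is a pure function of the task names so task
#'   indices are reproducible.
#' @export
multitask_registry <- function(records, modification = NULL) {
  needed <- c("id", "seq", "label", "task", "split")
  if (!all(needed %in% names(records))) {
    stop("records must have columns: ", paste(needed, collapse = ", "))
  }
  if (!all(records$split %in% c("train", "test"))) {
    stop("split must be 'train' or 'test'")
  }
  if (!all(records$label %in% c(0L, 1L))) stop("labels must be 0 or 1")
  task_names <- sort(unique(records$task))
  if (length(task_names) == 0L) stop("registry must contain at least one task")
  tasks <- lapply(task_names, function(tn) {
    sub <- records[records$task == tn, , drop = FALSE]
    mk <- function(sp) {
      d <- sub[sub$split == sp, c("id", "seq", "label", "task"), drop = FALSE]
      rownames(d) <- NULL
      d
    }
    list(task = tn, train = mk("train"), test = mk("test"))
  })
  names(tasks) <- task_names
  if (is.null(modification)) {
    modification <- ifelse(grepl("^(4mC|6mA):", task_names),
                           sub(":.*$", "", task_names), NA_character_)
    names(modification) <- task_names
  }
  structure(list(tasks = tasks, modification = modification),
            class = "mt_registry")
}

#' @export
print.mt_registry <- function(x, ...) {
  cat("Multi-task registry:", length(x$tasks), "task(s)\n")
  for (t in x$tasks) {
    cat(sprintf("  %-24s train %5d (%d+/%d-)  test %5d (%d+/%d-)\n",
                t$task, nrow(t$train), sum(t$train$label == 1L),
                sum(t$train$label == 0L), nrow(t$test),
                sum(t$test$label == 1L), sum(t$test$label == 0L)))
  }
  invisible(x)
}

#' Per-task class counts of a registry
#'
#' @param registry an `mt_registry`.
#' @return data.frame with one row per (task, split, label) and its count.
#' @export
registry_counts <- function(registry) {
  stopifnot(inherits(registry, "mt_registry"))
  out <- do.call(rbind, lapply(registry$tasks, function(t) {
    do.call(rbind, lapply(c("train", "test"), function(sp) {
      d <- t[[sp]]
      data.frame(task = t$task, split = sp, label = c(0L, 1L),
                 n = c(sum(d$label == 0L), sum(d$label == 1L)),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Check per-split class balance
#'
#' @param registry an `mt_registry`.
#' @return TRUE when every (task, split) has equal positive and negative
#'   counts, as in balanced benchmark designs.
#' @export
is_balanced <- function(registry) {
  cts <- registry_counts(registry)
  all(tapply(cts$n, paste(cts$task, cts$split), function(v) length(unique(v)) == 1L))
}

#' Read a multi-task dataset manifest
#'
#' The manifest is a UTF-8 TSV with header
#' `task  split  label  fasta_path`; each row points at one FASTA file of
#' one (task, split, class) cell. Relative `fasta_path`s are resolved
#' against the manifest's directory.
#'
#' @param path manifest TSV path.
#' @param policy alphabet policy passed to [read_fasta()].
#' @return An `mt_registry`.
#' @export
read_manifest <- function(path, policy = c("strict", "skip")) {
  policy <- match.arg(policy)
  if (!file.exists(path)) stop("manifest not found: ", path)
  man <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  needed <- c("task", "split", "label", "fasta_path")
  if (!all(needed %in% names(man))) {
    stop("manifest must have columns: ", paste(needed, collapse = ", "))
  }
  for (i in seq_len(nrow(man))) {
    if (!man$split[i] %in% c("train", "test")) {
      stop("manifest row ", i, ": unknown split '", man$split[i],
           "' (expected 'train' or 'test')")
    }
    if (!man$label[i] %in% c("0", "1")) {
      stop("manifest row ", i, ": label must be 0 or 1, got '", man$label[i], "'")
    }
  }
  key <- paste(man$task, man$split, man$label)
  if (anyDuplicated(key)) {
    stop("duplicate (task, split, label) manifest row: ",
         key[duplicated(key)][1L])
  }
  base <- dirname(normalizePath(path))
  recs <- lapply(seq_len(nrow(man)), function(i) {
    fp <- man$fasta_path[i]
    if (!file.exists(fp)) fp <- file.path(base, man$fasta_path[i])
    if (!file.exists(fp)) {
      stop("manifest row ", i, ": FASTA file not found: ", man$fasta_path[i])
    }
    d <- read_fasta(fp, task = man$task[i], label = as.integer(man$label[i]),
                    policy = policy)
    d$split <- man$split[i]
    d
  })
  multitask_registry(do.call(rbind, recs))
}

#' Read a single labeled-TSV dataset
#'
#' Alternative single-file input: a TSV with header
#' `id  task  split  label  seq`.
#'
#' @param path TSV path.
#' @param policy alphabet policy, see [validate_seqs()].
#' @return An `mt_registry`.
#' @export
read_labeled_tsv <- function(path, policy = c("strict", "skip")) {
  policy <- match.arg(policy)
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  needed <- c("id", "task", "split", "label", "seq")
  if (!all(needed %in% names(d))) {
    stop("labeled TSV must have columns: ", paste(needed, collapse = ", "))
  }
  if (!all(d$label %in% c("0", "1"))) stop("labels must be 0 or 1")
  v <- validate_seqs(d$seq, policy = policy, ids = paste0("record '", d$id, "'"))
  d <- d[v$keep, , drop = FALSE]
  d$seq <- v$seq
  d$label <- as.integer(d$label)
  multitask_registry(d)
}
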