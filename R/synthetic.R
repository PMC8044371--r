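#' Specification of a synthetic multi-task motif benchmark
#'
#' Describes K balanced two-class tasks of equal-length windows. Negatives
#' are i.i.d. background; positives carry a motif signal that is partly
#' shared across tasks (the shared motif, inserted with probability
#' `q_shared`) and partly task-specific (per-task motifs, probability
#' `q_task`), each inserted at a uniform-random non-overlapping position
#' (never the exact center) and mutated per position with rate `mu`. This
#' emulates the statistical structure of multi-species modification-site
#' benchmarks — balanced classes, short fixed windows, signal shared
#' between species — without any real genome content.
#'
#' @param n_tasks number of tasks K (default 4).
#' @param n_train,n_test per-class counts per split (defaults 200 / 100),
#'   scalars or length-K vectors.
#' @param length window length in nt (default 41).
#' @param shared_motif motif common to all tasks (default `"GACGTC"`).
#' @param task_motifs character vector of K task-specific motifs; by
#'   default drawn reproducibly from the seed.
#' @param q_shared,q_task insertion probabilities in positives (defaults
#'   0.9 and 0.5).
#' @param mu per-position motif mutation rate (default 0.05).
#' @param background base probabilities for A/C/G/T (default uniform).
#' @param task_names task names; default `task1..taskK`.
#' @param seed mandatory RNG seed.
#' @return A list of class `mt_synthetic_spec`.
#' @export
synthetic_spec <- function(n_tasks = 4L, n_train = 200L, n_test = 100L,
                           length = 41L, shared_motif = "GACGTC",
                           task_motifs = NULL, q_shared = 0.9, q_task = 0.5,
                           mu = 0.05, background = c(A = 0.25, C = 0.25,
                                                     G = 0.25, T = 0.25),
                           task_names = NULL, seed) {
  if (missing(seed)) stop("a seed is mandatory for synthetic data")
  n_tasks <- as.integer(n_tasks)
  if (n_tasks < 1L) stop("need at least one task")
  n_train <- rep_len(as.integer(n_train), n_tasks)
  n_test <- rep_len(as.integer(n_test), n_tasks)
  if (is.null(task_names)) task_names <- paste0("task", seq_len(n_tasks))
  if (anyDuplicated(task_names)) stop("task names must be unique")
  check_motif <- function(m) {
    if (grepl("[^ACGT]", m)) stop("motifs must be A/C/G/T strings: ", m)
    if (nchar(m) >= length) stop("motif '", m, "' does not fit in length ", length)
    m
  }
  check_motif(shared_motif)
  if (is.null(task_motifs)) {
    set.seed(as.integer(seed) + 1000L)
    task_motifs <- vapply(seq_len(n_tasks), function(i) {
      repeat {
        m <- paste(sample(c("A", "C", "G", "T"), nchar(shared_motif),
                          replace = TRUE), collapse = "")
        if (m != shared_motif) return(m)
      }
    }, character(1L))
  }
  task_motifs <- rep_len(task_motifs, n_tasks)
  vapply(task_motifs, check_motif, character(1L))
  if (nchar(shared_motif) + max(nchar(task_motifs)) > length - 1L) {
    stop("the two motifs cannot be placed without overlap in windows of length ",
         length)
  }
  stopifnot(all(c(q_shared, q_task, mu) >= 0), all(c(q_shared, q_task, mu) <= 1))
  background <- background / sum(background)
  structure(list(n_tasks = n_tasks, n_train = n_train, n_test = n_test,
                 length = as.integer(length), shared_motif = shared_motif,
                 task_motifs = task_motifs, q_shared = q_shared,
                 q_task = q_task, mu = mu, background = background,
                 task_names = task_names, seed = as.integer(seed)),
            class = "mt_synthetic_spec")
}

rand_bases <- function(n, background) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = background)
}

mutate_motif <- function(chars, mu) {
  hit <- stats::runif(length(chars)) < mu
  if (any(hit)) {
    chars[hit] <- vapply(chars[hit], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1L)
    }, character(1L))
  }
  chars
}

## choose non-overlapping start positions for the motifs to insert,
## avoiding the exact center position of the window
place_motifs <- function(length, widths) {
  center <- (length + 1L) %/% 2L
  ok_starts <- function(w) {
    s <- seq_len(length - w + 1L)
    s[s + w - 1L < center | s > center]  # window must not cover the center
  }
  if (base::length(widths) == 1L) {
    s <- ok_starts(widths[1L])
    if (base::length(s) == 0L) stop("motif cannot be placed off-center")
    return(sample(s, 1L))
  }
  # two motifs: rejection-sample a non-overlapping off-center pair
  s1_all <- ok_starts(widths[1L]); s2_all <- ok_starts(widths[2L])
  if (base::length(s1_all) == 0L || base::length(s2_all) == 0L) {
    stop("motifs cannot be placed off-center in this window length")
  }
  for (i in seq_len(200L)) {
    s1 <- sample(s1_all, 1L)
    s2 <- sample(s2_all, 1L)
    if (s1 + widths[1L] - 1L < s2 || s2 + widths[2L] - 1L < s1) return(c(s1, s2))
  }
  stop("could not place both motifs without overlap in window length ", length)
}

#' Generate a synthetic multi-task dataset
#'
#' Deterministic given the spec's seed: the same spec yields byte-identical
#' records. Every (task, split) is exactly class balanced.
#'
#' @param spec an `mt_synthetic_spec`.
#' @return A list of class `mt_synthetic`: `registry` (an `mt_registry`),
#'   `spec` and `provenance` (per-record ground-truth motif placements).
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "mt_synthetic_spec"))
  set.seed(spec$seed)
  prov <- list()
  recs <- list()
  for (k in seq_len(spec$n_tasks)) {
    tn <- spec$task_names[k]
    for (split in c("train", "test")) {
      n_per_class <- if (split == "train") spec$n_train[k] else spec$n_test[k]
      for (label in c(1L, 0L)) {
        n <- n_per_class
        if (n == 0L) next
        seqs <- character(n)
        placements <- vector("list", n)
        for (i in seq_len(n)) {
          chars <- rand_bases(spec$length, spec$background)
          placed <- list()
          if (label == 1L) {
            use_shared <- stats::runif(1) < spec$q_shared
            use_task <- stats::runif(1) < spec$q_task
            motifs <- list()
            if (use_shared) motifs$shared <- spec$shared_motif
            if (use_task) motifs$task <- spec$task_motifs[k]
            if (length(motifs) > 0L) {
              widths <- vapply(motifs, nchar, 1L)
              starts <- place_motifs(spec$length, widths)
              for (j in seq_along(motifs)) {
                mchars <- mutate_motif(strsplit(motifs[[j]], "")[[1L]], spec$mu)
                chars[starts[j] + seq_along(mchars) - 1L] <- mchars
                placed[[names(motifs)[j]]] <- starts[j]
              }
            }
          }
          seqs[i] <- paste(chars, collapse = "")
          placements[[i]] <- placed
        }
        ids <- sprintf("%s_%s_%s_%04d", tn, split,
                       ifelse(label == 1L, "pos", "neg"), seq_len(n))
        recs[[length(recs) + 1L]] <- data.frame(
          id = ids, seq = seqs, label = label, task = tn, split = split,
          stringsAsFactors = FALSE)
        prov[[paste(tn, split, label, sep = ":")]] <- placements
      }
    }
  }
  registry <- multitask_registry(do.call(rbind, recs))
  structure(list(registry = registry, spec = spec, provenance = prov),
            class = "mt_synthetic")
}

#' Export a synthetic dataset to FASTA + manifest
#'
#' Writes one single-line FASTA per (task, split, class), a manifest TSV
#' readable by [read_manifest()], and a provenance JSON holding the full
#' generator spec (from which the dataset can be regenerated identically).
#'
#' @param dataset an `mt_synthetic` (or plain `mt_registry`).
#' @param out_dir output directory, created if needed.
#' @return The manifest path, invisibly.
#' @export
export_dataset <- function(dataset, out_dir) {
  registry <- if (inherits(dataset, "mt_synthetic")) dataset$registry else dataset
  stopifnot(inherits(registry, "mt_registry"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (tn in names(registry$tasks)) {
    for (split in c("train", "test")) {
      d <- registry$tasks[[tn]][[split]]
      for (label in c(0L, 1L)) {
        sub <- d[d$label == label, , drop = FALSE]
        if (nrow(sub) == 0L) next
        safe <- gsub("[^A-Za-z0-9._-]", "_", tn)
        fn <- sprintf("%s_%s_%s.fasta", safe, split,
                      ifelse(label == 1L, "pos", "neg"))
        write_fasta(sub, file.path(out_dir, fn))
        rows[[length(rows) + 1L]] <- data.frame(
          task = tn, split = split, label = label, fasta_path = fn,
          stringsAsFactors = FALSE)
      }
    }
  }
  man <- do.call(rbind, rows)
  man_path <- file.path(out_dir, "manifest.tsv")
  utils::write.table(man, man_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (inherits(dataset, "mt_synthetic")) {
    jsonlite::write_json(unclass(dataset$spec),
                         file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(man_path)
}

#' Regenerate a dataset from an exported provenance file
#'
#' @param path provenance JSON written by [export_dataset()].
#' @return An `mt_synthetic` identical to the original.
#' @export
regenerate_dataset <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- synthetic_spec(n_tasks = raw$n_tasks, n_train = raw$n_train,
                         n_test = raw$n_test, length = raw$length,
                         shared_motif = raw$shared_motif,
                         task_motifs = raw$task_motifs,
                         q_shared = raw$q_shared, q_task = raw$q_task,
                         mu = raw$mu, background = unlist(raw$background),
                         task_names = raw$task_names, seed = raw$seed)
  generate_dataset(spec)
}
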