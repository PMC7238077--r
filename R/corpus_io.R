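#' Construct a labeled document
#'
#' The unit of training and testing: one text fragment with one label per
#' token and the identifier of the patient the fragment belongs to.
#'
#' @param doc_id,patient_id character scalars.
#' @param tokens character vector of non-empty tokens, length >= 1.
#' @param labels character vector of label names, same length as `tokens`.
#' @param scheme label scheme used for validation (default
#'   [build_label_scheme()]).
#' @return an object of class `labeled_document`.
#' @export
labeled_document <- function(doc_id, patient_id, tokens, labels,
                             scheme = build_label_scheme()) {
  stopifnot(is.character(doc_id), length(doc_id) == 1L,
            is.character(patient_id), length(patient_id) == 1L)
  if (length(tokens) < 1L)
    stop_phideid("document '%s' has no tokens", doc_id)
  if (length(tokens) != length(labels))
    stop_phideid("document '%s': %d tokens but %d labels",
                 doc_id, length(tokens), length(labels))
  if (any(!nzchar(tokens)) || anyNA(tokens))
    stop_phideid("document '%s' contains an empty token", doc_id)
  label_index(scheme, labels) # validates labels
  structure(list(doc_id = doc_id, patient_id = patient_id,
                 tokens = as.character(tokens), labels = as.character(labels)),
            class = "labeled_document")
}

#' @export
print.labeled_document <- function(x, ...) {
  cat(sprintf("<labeled_document %s (patient %s): %d tokens, %d PHI>\n",
              x$doc_id, x$patient_id, length(x$tokens),
              sum(x$labels != .non_phi_label)))
  invisible(x)
}

#' Read a token/label corpus file
#'
#' Parses the package's CoNLL-style corpus dialect: each document starts with
#' a header line `#doc <doc_id> <patient_id>`, followed by one
#' `<token>\t<label>` line per token; blank lines are permitted between
#' documents. Labels are validated against the scheme.
#'
#' @param path file path (UTF-8 text).
#' @param scheme label scheme for validation.
#' @return list of [labeled_document()]s in file order.
#' @seealso [write_token_label_file()]
#' @export
read_token_label_file <- function(path, scheme = build_label_scheme()) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  docs <- list()
  cur_header <- NULL; cur_tok <- character(0); cur_lab <- character(0)
  header_line <- 0L

  flush_doc <- function() {
    if (is.null(cur_header)) return()
    if (length(cur_tok) == 0L)
      stop_phideid("line %d: document '%s' has no token lines",
                   header_line, cur_header[1])
    docs[[length(docs) + 1L]] <<- labeled_document(
      cur_header[1], cur_header[2], cur_tok, cur_lab, scheme = scheme)
  }

  for (i in seq_along(lines)) {
    line <- lines[i]
    if (!nzchar(line)) next
    if (startsWith(line, "#doc ")) {
      flush_doc()
      parts <- strsplit(sub("^#doc ", "", line), " ", fixed = TRUE)[[1]]
      if (length(parts) != 2L)
        stop_phideid("line %d: malformed header '%s'", i, line)
      cur_header <- parts; header_line <- i
      cur_tok <- character(0); cur_lab <- character(0)
    } else {
      if (is.null(cur_header))
        stop_phideid("line %d: token line before any '#doc' header", i)
      parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
      if (length(parts) != 2L || !nzchar(parts[1]))
        stop_phideid("line %d: malformed token line '%s'", i, line)
      if (!parts[2] %in% scheme$labels)
        stop_phideid("line %d: unknown label '%s'", i, parts[2])
      cur_tok <- c(cur_tok, parts[1]); cur_lab <- c(cur_lab, parts[2])
    }
  }
  flush_doc()
  docs
}

#' Write a token/label corpus file
#'
#' Inverse of [read_token_label_file()]; a write followed by a read restores
#' the corpus exactly.
#'
#' @param corpus list of [labeled_document()]s.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_token_label_file <- function(corpus, path) {
  out <- unlist(lapply(corpus, function(d) {
    c(sprintf("#doc %s %s", d$doc_id, d$patient_id),
      paste(d$tokens, d$labels, sep = "\t"),
      "")
  }))
  writeLines(out, path, useBytes = FALSE)
  invisible(path)
}

#' Split long documents into training fragments
#'
#' Documents longer than `max_len` tokens are cut into consecutive fragments
#' of at most `max_len` tokens (doc_id suffixed `.1`, `.2`, ...). Used to cap
#' the length of training sequences.
#'
#' @param corpus list of labeled documents.
#' @param max_len maximum fragment length in tokens (default 100).
#' @return list of labeled documents, each with at most `max_len` tokens.
#' @export
split_fragments <- function(corpus, max_len = 100L) {
  stopifnot(is_count(max_len), max_len >= 1)
  out <- list()
  for (d in corpus) {
    n <- length(d$tokens)
    if (n <= max_len) { out[[length(out) + 1L]] <- d; next }
    starts <- seq(1L, n, by = max_len)
    for (k in seq_along(starts)) {
      i0 <- starts[k]; i1 <- min(n, i0 + max_len - 1L)
      out[[length(out) + 1L]] <- labeled_document(
        paste0(d$doc_id, ".", k), d$patient_id,
        d$tokens[i0:i1], d$labels[i0:i1])
    }
  }
  out
}

#' Stub converter for i2b2 2014 XML
#'
#' The 2014 de-identification challenge corpus is access-restricted; this
#' converter is declared for users who hold a data-use agreement but is not
#' implemented here.
#'
#' @param xml_path path to an i2b2 2014 XML record.
#' @export
convert_i2b2_xml <- function(xml_path) {
  stop_phideid(paste("not implemented: the i2b2 2014 corpus is",
                     "access-restricted; convert it to the token/label",
                     "format externally"))
}

#' Partition a corpus into patient-disjoint subsets
#'
#' Assigns whole patients (all documents sharing a `patient_id`) to `k`
#' subsets, balancing subset token counts greedily: patients are taken
#' largest-first (ties shuffled by `seed`) and each is placed on the
#' currently smallest subset.
#'
#' @param corpus list of labeled documents.
#' @param k number of subsets (1 <= k <= number of distinct patients).
#' @param seed integer seed controlling tie-shuffling.
#' @return object of class `corpus_partition`: list with `subsets` (list of
#'   `k` document lists) and `seed`.
#' @export
partition_by_patient <- function(corpus, k, seed = 1L) {
  stopifnot(is_count(k), k >= 1)
  pids <- vapply(corpus, function(d) d$patient_id, character(1))
  sizes <- vapply(corpus, function(d) length(d$tokens), integer(1))
  pat_tokens <- tapply(sizes, pids, sum)
  if (length(pat_tokens) < k)
    stop_phideid("k = %d exceeds the number of distinct patients (%d)",
                 k, length(pat_tokens))
  ord <- with_seed(derive_seed(seed, 211L), {
    shuffled <- sample(names(pat_tokens))
    shuffled[order(pat_tokens[shuffled], decreasing = TRUE)]
  })
  assign_to <- integer(length(ord)); names(assign_to) <- ord
  load <- numeric(k)
  for (p in ord) {
    j <- which.min(load)
    assign_to[[p]] <- j
    load[j] <- load[j] + pat_tokens[[p]]
  }
  subsets <- lapply(seq_len(k), function(j) {
    corpus[pids %in% names(assign_to)[assign_to == j]]
  })
  structure(list(subsets = subsets, seed = as.integer(seed)),
            class = "corpus_partition")
}

#' @export
print.corpus_partition <- function(x, ...) {
  toks <- vapply(x$subsets, function(s)
    sum(vapply(s, function(d) length(d$tokens), integer(1))), numeric(1))
  cat(sprintf("<corpus_partition: %d subsets, token counts %s>\n",
              length(x$subsets), paste(toks, collapse = "/")))
  invisible(x)
}
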