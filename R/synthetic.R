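# Seeded generator of annotated pseudo-clinical corpora with the statistical
# shape of the study data: natural-language-like token streams at ~2.8% PHI
# tokens drawn from the 23 attested PHI classes, multiple records per
# patient, recurring surrogate names, and digit-bearing PHI produced by
# per-class format grammars so the character channel carries real signal.

#' Specification of a synthetic corpus
#'
#' @param n_patients number of patients.
#' @param records_per_patient integer range `c(min, max)` of records per
#'   patient.
#' @param tokens_per_record integer range `c(min, max)` of tokens per record.
#' @param phi_token_rate target fraction of PHI tokens (default 0.028,
#'   matching roughly 17,000 PHI among 598,000 training tokens).
#' @param phi_class_weights named numeric vector of sampling weights over the
#'   23 attested PHI labels (default uniform); names must be exactly those
#'   labels and weights must sum to 1.
#' @param vocab_size size of the filler-prose vocabulary (core clinical
#'   vocabulary extended by seeded pseudo-words).
#' @param line_tokens integer range of tokens per generated line; each line
#'   becomes one labeled document (training fragment).
#' @param seed integer seed; the same spec yields the identical corpus.
#' @return object of class `corpus_spec`.
#' @export
corpus_spec <- function(n_patients = 50L,
                        records_per_patient = c(2L, 6L),
                        tokens_per_record = c(100L, 400L),
                        phi_token_rate = 0.028,
                        phi_class_weights = NULL,
                        vocab_size = 2000L,
                        line_tokens = c(6L, 18L),
                        seed = 1L) {
  scheme <- build_label_scheme()
  present <- scheme$present_phi_labels
  if (is.null(phi_class_weights)) {
    phi_class_weights <- setNames(rep(1 / length(present), length(present)),
                                  present)
  }
  if (!setequal(names(phi_class_weights), present))
    stop_phideid("phi_class_weights must be named by the %d attested PHI labels",
                 length(present))
  if (abs(sum(phi_class_weights) - 1) > 1e-8)
    stop_phideid("phi_class_weights must sum to 1")
  stopifnot(n_patients >= 1, length(records_per_patient) == 2L,
            records_per_patient[1] >= 1L,
            records_per_patient[1] <= records_per_patient[2],
            length(tokens_per_record) == 2L, tokens_per_record[1] >= 10L,
            tokens_per_record[1] <= tokens_per_record[2],
            phi_token_rate > 0, phi_token_rate < 1,
            vocab_size >= 300L,
            length(line_tokens) == 2L, line_tokens[1] >= 4L,
            line_tokens[1] <= line_tokens[2])
  structure(list(n_patients = as.integer(n_patients),
                 records_per_patient = as.integer(records_per_patient),
                 tokens_per_record = as.integer(tokens_per_record),
                 phi_token_rate = phi_token_rate,
                 phi_class_weights = phi_class_weights[present],
                 vocab_size = as.integer(vocab_size),
                 line_tokens = as.integer(line_tokens),
                 seed = as.integer(seed)),
            class = "corpus_spec")
}

# ---- entity surface grammars ----------------------------------------------

digits_token <- function(n) paste(sample(0:9, n, replace = TRUE),
                                  collapse = "")

split_ws <- function(x) strsplit(x, " ", fixed = TRUE)[[1]]

# One surface realization (a token vector) of a PHI entity of class `label`.
# `ctx` carries the per-patient identity so names recur across records.
gen_entity_tokens <- function(label, ctx) {
  switch(label,
    patient = if (runif(1) < 0.7) c(ctx$first, ctx$last)
              else sample(c(ctx$first, ctx$last), 1),
    clinician = if (runif(1) < 0.5) sample(.lex_last, 1)
                else c(sample(.lex_first, 1), sample(.lex_last, 1)),
    username = paste0(tolower(substr(sample(.lex_first, 1), 1, 1)),
                      tolower(sample(.lex_last, 1)), sample(10:99, 1)),
    profession = sample(.lex_profession, 1),
    hospital = c(sample(.lex_city, 1),
                 split_ws(sample(.lex_hospital_mid, 1)),
                 split_ws(sample(.lex_hospital_suffix, 1))),
    organization = c(sample(.lex_org_stem, 1), sample(.lex_org_suffix, 1)),
    street = c(digits_token(sample(2:4, 1)), sample(.lex_city, 1),
               sample(.lex_street_suffix, 1)),
    city = sample(.lex_city, 1),
    state = sample(.lex_state, 1),
    country = sample(.lex_country, 1),
    zip = digits_token(5),
    "location-other" = c(sample(.lex_org_stem, 1),
                         sample(c("Park", "Plaza", "Tower", "Mall"), 1)),
    date = gen_date_tokens(),
    phone = ,
    fax = gen_phone_tokens(),
    email = c(tolower(sample(.lex_first, 1)), ".",
              tolower(sample(.lex_last, 1)), "@",
              sample(.lex_domains, 1), ".", "com"),
    url = c("www", ".", tolower(sample(.lex_org_stem, 1)), ".",
            sample(c("org", "com", "net"), 1)),
    "medical-record-number" = digits_token(sample(6:8, 1)),
    "health-plan-number" = paste0("HP", digits_token(6)),
    "device-id" = paste0(paste(sample(LETTERS, 2), collapse = ""),
                         digits_token(2), "-", digits_token(3)),
    "biometric-id" = paste0("B", digits_token(7)),
    "id-number" = digits_token(sample(5:9, 1)),
    age = as.character(sample(18:95, 1)),
    stop_phideid("no surface grammar for label '%s'", label)
  )
}

gen_date_tokens <- function() {
  y <- sample(1990:2015, 1); mo <- sample(1:12, 1); d <- sample(1:28, 1)
  switch(sample(5, 1),
    sprintf("%04d-%02d-%02d", y, mo, d),
    c(sprintf("%02d", mo), "/", sprintf("%02d", d), "/", sprintf("%04d", y)),
    c(.lex_months[mo], as.character(d), ",", as.character(y)),
    c(as.character(d), .lex_months_abbr[mo], as.character(y)),
    sprintf("%02d-%02d-%04d", mo, d, y))
}

gen_phone_tokens <- function() {
  a <- digits_token(3); b <- digits_token(3); c4 <- digits_token(4)
  switch(sample(3, 1),
    c("(", a, ")", paste0(b, "-", c4)),
    paste0(a, "-", b, "-", c4),
    c(a, paste0(b, "-", c4)))
}

# Non-PHI cue tokens that often precede an entity of the given class.
.entity_cues <- list(
  patient = list(c("patient"), c("Mr", "."), c("Ms", ".")),
  clinician = list(c("Dr", "."), c("seen", "by")),
  username = list(c("user"), c("entered", "by")),
  profession = list(c("works", "as"), c("employed", "as")),
  hospital = list(c("at"), c("admitted", "to")),
  organization = list(c("through"), c("insured", "by")),
  street = list(c("at"), c("address")),
  city = list(c("in"), c("from")),
  state = list(c("in")),
  country = list(c("from"), c("in")),
  zip = list(c("zip")),
  "location-other" = list(c("near"), c("at")),
  date = list(c("on"), c("since"), c("dated")),
  phone = list(c("phone"), c("call"), c("contact", "at")),
  fax = list(c("fax"), c("faxed", "to")),
  email = list(c("email"), c("sent", "to")),
  url = list(),
  "medical-record-number" = list(c("MRN"), c("record")),
  "health-plan-number" = list(c("plan"), c("policy")),
  "device-id" = list(c("device"), c("implant")),
  "biometric-id" = list(c("biometric")),
  "id-number" = list(c("ID"), c("number")),
  age = list(c("age"), c("aged"))
)

# ---- filler prose channel ---------------------------------------------------

make_filler_model <- function(vocab_size) {
  extra <- vocab_size - length(.lex_filler)
  vocab <- .lex_filler
  if (extra > 0) {
    cons <- c("b", "c", "d", "f", "g", "k", "l", "m", "n", "p", "r", "s",
              "t", "v", "z", "ch", "st", "tr", "pl", "br")
    vow <- c("a", "e", "i", "o", "u", "ia", "ou", "ea")
    n_syl <- sample(2:4, extra, replace = TRUE)
    pseudo <- vapply(n_syl, function(k) {
      paste0(paste0(sample(cons, k, replace = TRUE),
                    sample(vow, k, replace = TRUE)), collapse = "")
    }, character(1))
    # drop random syllable combinations that collide with real slurs/terms
    blocked <- c("nazi", "rape", "kike", "coon", "paki")
    pseudo <- pseudo[!vapply(pseudo, function(w)
      any(vapply(blocked, grepl, logical(1), x = w, fixed = TRUE)),
      logical(1))]
    vocab <- unique(c(vocab, pseudo))
  }
  # sparse bigram chain: each word gets a fixed set of successor candidates
  succ <- matrix(sample.int(length(vocab), length(vocab) * 8L,
                            replace = TRUE),
                 nrow = length(vocab))
  list(vocab = vocab, succ = succ)
}

# ---- corpus generation ------------------------------------------------------

#' Generate a synthetic annotated corpus
#'
#' Produces labeled pseudo-clinical documents: filler prose from a seeded
#' bigram sampler, interleaved with PHI entities drawn from per-class
#' surrogate lexicons and format grammars, often preceded by a class-typical
#' (non-PHI) cue word. Every line of a record becomes one labeled document
#' (one training fragment); all lines of a patient's records share the
#' patient identifier, and a patient's own name recurs across their records.
#' The whole corpus is a deterministic function of the spec.
#'
#' @param spec a [corpus_spec()].
#' @return list of [labeled_document()]s.
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "corpus_spec"))
  scheme <- build_label_scheme()
  with_seed(derive_seed(spec$seed, 104729L), {
    fm <- make_filler_model(spec$vocab_size)
    classes <- names(spec$phi_class_weights)
    wts <- as.numeric(spec$phi_class_weights)

    # estimate mean PHI-entity length and cue length to calibrate the
    # per-token insertion probability for the target PHI rate
    probe <- replicate(300, {
      lb <- sample(classes, 1, prob = wts)
      ctx <- list(first = sample(.lex_first, 1), last = sample(.lex_last, 1))
      ent <- gen_entity_tokens(lb, ctx)
      cues <- .entity_cues[[lb]]
      cue_len <- if (length(cues) > 0 && runif(1) < 0.6)
        length(cues[[sample(length(cues), 1)]]) else 0L
      c(length(ent), cue_len)
    })
    L <- mean(probe[1, ]); cbar <- mean(probe[2, ])
    f <- spec$phi_token_rate
    r_ins <- f / (L - f * (L + cbar - 1))
    if (!is.finite(r_ins) || r_ins <= 0 || r_ins >= 1)
      stop_phideid("infeasible spec: PHI rate %.3f not reachable", f)

    docs <- list()
    for (pi in seq_len(spec$n_patients)) {
      pid <- sprintf("PT%04d", pi)
      ctx <- list(first = sample(.lex_first, 1), last = sample(.lex_last, 1))
      n_rec <- sample(seq(spec$records_per_patient[1],
                          spec$records_per_patient[2]), 1)
      for (ri in seq_len(n_rec)) {
        n_tok <- sample(seq(spec$tokens_per_record[1],
                            spec$tokens_per_record[2]), 1)
        emitted <- 0L
        li <- 0L
        cur <- sample.int(length(fm$vocab), 1)
        while (emitted < n_tok) {
          li <- li + 1L
          target <- sample(seq(spec$line_tokens[1], spec$line_tokens[2]), 1)
          toks <- character(0); labs <- character(0)
          first_tok <- TRUE
          while (length(toks) < target) {
            if (runif(1) < r_ins) {
              lb <- sample(classes, 1, prob = wts)
              cues <- .entity_cues[[lb]]
              if (length(cues) > 0 && runif(1) < 0.6) {
                cue <- cues[[sample(length(cues), 1)]]
                toks <- c(toks, cue)
                labs <- c(labs, rep(.non_phi_label, length(cue)))
              }
              ent <- gen_entity_tokens(lb, ctx)
              toks <- c(toks, ent)
              labs <- c(labs, rep(lb, length(ent)))
            } else {
              w <- fm$vocab[cur]
              if (first_tok)
                w <- paste0(toupper(substr(w, 1, 1)), substring(w, 2))
              if (runif(1) < 0.05) {
                toks <- c(toks, sample(c(",", "."), 1))
                labs <- c(labs, .non_phi_label)
                cur <- sample.int(length(fm$vocab), 1)
              } else {
                toks <- c(toks, w)
                labs <- c(labs, .non_phi_label)
                cur <- fm$succ[cur, sample.int(ncol(fm$succ), 1)]
              }
            }
            first_tok <- FALSE
          }
          docs[[length(docs) + 1L]] <- labeled_document(
            sprintf("%s-R%02d-L%03d", pid, ri, li), pid, toks, labs,
            scheme = scheme)
          emitted <- emitted + length(toks)
        }
      }
    }
    docs
  })
}

#' Patient-disjoint train/test split
#'
#' Assigns whole patients to the test set so that its token share comes as
#' close as possible to `test_fraction`; no patient appears on both sides.
#'
#' @param corpus list of labeled documents.
#' @param test_fraction target fraction of tokens in the test set (default
#'   0.39, the study's test share).
#' @param seed integer seed for the patient order.
#' @return list with elements `train` and `test` (document lists).
#' @export
split_train_test <- function(corpus, test_fraction = 0.39, seed = 1L) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  pids <- vapply(corpus, `[[`, character(1), "patient_id")
  sizes <- vapply(corpus, function(d) length(d$tokens), integer(1))
  pat_tokens <- tapply(sizes, pids, sum)
  if (length(pat_tokens) < 2L)
    stop_phideid("need at least 2 patients for a patient-disjoint split")
  ord <- with_seed(derive_seed(seed, 7103L), sample(names(pat_tokens)))
  share <- cumsum(pat_tokens[ord]) / sum(pat_tokens)
  n_test <- which.min(abs(share - test_fraction))
  n_test <- max(1L, min(n_test, length(ord) - 1L))
  test_pids <- ord[seq_len(n_test)]
  list(train = corpus[!pids %in% test_pids],
       test = corpus[pids %in% test_pids])
}

# Realized PHI-token fraction of a corpus.
phi_token_fraction <- function(corpus) {
  labs <- unlist(lapply(corpus, `[[`, "labels"))
  mean(labs != .non_phi_label)
}
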