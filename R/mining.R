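# Association-rule mining: equal-frequency discretization, level-wise
# Apriori frequent-itemset search with the downward-closure prune, rule
# derivation with a restricted consequent vocabulary, and the two
# study-level analyses (question-level and behavior-level associations).

#' Equal-frequency discretization into low/moderate/high
#'
#' Nearest-rank quantile bin edges; ties are assigned to the lower bin, so
#' bin counts are as close to equal as ties permit. Constant columns (or
#' columns with fewer distinct values than bins) cannot be binned and
#' return NULL, flagging the column for exclusion from mining.
#'
#' @param x numeric vector (NAs preserved)
#' @param k number of bins (default 3)
#' @param labels bin labels, ordered by value
#' @return character vector of bin labels, or NULL for a constant column
#' @export
discretize_equal_frequency <- function(x, k = 3L,
                                       labels = c("low", "moderate", "high")) {
  stopifnot(k >= 2L, length(labels) == k)
  obs <- x[!is.na(x)]
  if (length(unique(obs)) < k) return(NULL)
  # nearest-rank quantile edges; duplicate edges advance to the next
  # distinct value so every bin label stays reachable under heavy ties
  srt <- sort(obs)
  edges <- srt[pmax(1L, ceiling(length(srt) * seq_len(k - 1L) / k))]
  for (j in seq_along(edges)[-1]) {
    if (edges[j] <= edges[j - 1]) {
      nxt <- srt[srt > edges[j - 1]]
      if (length(nxt) == 0) return(NULL)
      edges[j] <- nxt[1]
    }
  }
  out <- rep(NA_character_, length(x))
  idx <- findInterval(x, c(-Inf, edges), left.open = TRUE) # ties -> lower bin
  out[!is.na(x)] <- labels[pmin(idx[!is.na(x)] + 0L, k)]
  out
}

#' Apriori frequent-itemset mining
#'
#' Level-wise candidate generation with the downward-closure prune: every
#' (k-1)-subset of a size-k candidate must be frequent. Supports are exact
#' transaction fractions.
#'
#' @param transactions list of character vectors (itemsets)
#' @param min_support minimum support in (0, 1]
#' @param max_size stop the level-wise search at itemsets of this size
#'   (Inf = exhaustive); with many correlated items a cap keeps the search
#'   tractable at low support floors
#' @return data.table with columns items (list), size, support
#' @export
apriori_frequent_itemsets <- function(transactions, min_support,
                                      max_size = Inf) {
  if (length(transactions) == 0) stop("no transactions")
  stopifnot(min_support > 0, min_support <= 1)
  transactions <- lapply(transactions, function(tr) sort(unique(as.character(tr))))
  n <- length(transactions)
  items <- sort(unique(unlist(transactions)))
  # incidence matrix items x transactions
  inc <- vapply(transactions, function(tr) items %in% tr,
                logical(length(items)))
  if (is.null(dim(inc))) inc <- matrix(inc, nrow = length(items))
  rownames(inc) <- items
  supp1 <- rowMeans(inc)
  frequent <- list()
  Lk <- lapply(items[supp1 >= min_support], identity)
  supp_k <- supp1[supp1 >= min_support]
  if (length(Lk) > 0) {
    frequent[[1]] <- data.table::data.table(
      items = Lk, size = 1L, support = as.numeric(supp_k))
  }
  k <- 1L
  while (length(Lk) > 1 && k < max_size) {
    keys <- vapply(Lk, paste, character(1), collapse = "\r")
    cand <- list()
    # join step: pairs sharing the first k-1 items
    prefix <- vapply(Lk, function(s) paste(head(s, k - 1L), collapse = "\r"),
                     character(1))
    ord <- order(prefix, keys)
    Lk <- Lk[ord]; prefix <- prefix[ord]
    for (i in seq_along(Lk)) {
      j <- i + 1L
      while (j <= length(Lk) && prefix[j] == prefix[i]) {
        cand[[length(cand) + 1L]] <- sort(union(Lk[[i]], Lk[[j]]))
        j <- j + 1L
      }
    }
    if (length(cand) == 0) break
    cand <- unique(cand)
    # prune step: all (k)-subsets of a (k+1)-candidate must be frequent
    freq_keys <- vapply(Lk, paste, character(1), collapse = "\r")
    ok <- vapply(cand, function(s) {
      subs <- vapply(seq_along(s), function(d)
        paste(s[-d], collapse = "\r"), character(1))
      all(subs %in% freq_keys)
    }, logical(1))
    cand <- cand[ok]
    if (length(cand) == 0) break
    supp <- vapply(cand, function(s) mean(colSums(inc[s, , drop = FALSE]) == length(s)),
                   numeric(1))
    keep <- supp >= min_support
    Lk <- cand[keep]
    if (length(Lk) > 0) {
      frequent[[k + 1L]] <- data.table::data.table(
        items = Lk, size = k + 1L, support = supp[keep])
    }
    k <- k + 1L
  }
  if (length(frequent) == 0)
    return(data.table::data.table(items = list(), size = integer(),
                                  support = numeric()))
  data.table::rbindlist(frequent)
}

#' Derive association rules with a restricted consequent vocabulary
#'
#' Emits rules `antecedent -> consequent` where the consequent is a single
#' item from `consequent_vocab`, the antecedent contains no vocabulary
#' item, and confidence = support(antecedent + consequent) /
#' support(antecedent) meets `min_confidence`.
#'
#' @param itemsets output of [apriori_frequent_itemsets()]
#' @param min_confidence minimum confidence in (0, 1]
#' @param consequent_vocab character vector of allowed consequent items
#' @return data.table: antecedent (list), consequent, support, confidence
#' @export
derive_rules <- function(itemsets, min_confidence, consequent_vocab) {
  if (length(consequent_vocab) == 0) stop("empty consequent vocabulary")
  its <- data.table::as.data.table(itemsets)
  if (nrow(its) == 0)
    return(data.table::data.table(antecedent = list(), consequent = character(),
                                  support = numeric(), confidence = numeric()))
  key <- vapply(its$items, paste, character(1), collapse = "\r")
  supp_of <- stats::setNames(its$support, key)
  rows <- list()
  for (i in seq_len(nrow(its))) {
    s <- its$items[[i]]
    if (length(s) < 2) next
    cons <- s[s %in% consequent_vocab]
    if (length(cons) != 1) next
    ant <- setdiff(s, cons)
    ant_supp <- supp_of[paste(sort(ant), collapse = "\r")]
    if (is.na(ant_supp)) next
    conf <- its$support[i] / ant_supp
    if (conf >= min_confidence) {
      rows[[length(rows) + 1L]] <- data.table::data.table(
        antecedent = list(sort(ant)), consequent = cons,
        support = its$support[i], confidence = conf)
    }
  }
  if (length(rows) == 0)
    return(data.table::data.table(antecedent = list(), consequent = character(),
                                  support = numeric(), confidence = numeric()))
  data.table::rbindlist(rows)[order(-support, -confidence)]
}

#' Question-level loneliness associations
#'
#' Encodes each participant's raw UCLA responses as items `"Qk>=3"` for
#' ratings of 3 or 4 plus a loneliness-level item, then mines rules whose
#' consequent is the level. Optionally runs the iterative
#' raise-support-until-empty search: starting from `min_support`, the
#' support floor is raised in 1-point steps and the largest support still
#' yielding at least one rule is reported.
#'
#' @param responses participants x 20 matrix (or list) of raw item ratings
#' @param levels character vector of "LL"/"HL" per participant
#' @param min_support,min_confidence thresholds (study values: 0.38, 0.90)
#' @param search_optimal_support run the raise-support search from
#'   `min_support` upward
#' @param step support search step (1 percentage point)
#' @return list: `rules`, `transactions`, and `optimal_support` (NA unless
#'   the search is run)
#' @export
mine_question_associations <- function(responses, levels,
                                       min_support = 0.38,
                                       min_confidence = 0.90,
                                       search_optimal_support = FALSE,
                                       step = 0.01) {
  if (is.list(responses) && !is.data.frame(responses))
    responses <- do.call(rbind, responses)
  responses <- as.matrix(responses)
  stopifnot(nrow(responses) == length(levels), ncol(responses) == 20)
  transactions <- lapply(seq_len(nrow(responses)), function(i) {
    hot <- which(responses[i, ] >= 3)
    items <- if (length(hot)) paste0("Q", hot, ">=3") else character(0)
    c(items, paste0("level=", levels[i]))
  })
  vocab <- c("level=HL", "level=LL")
  mine_at <- function(ms) {
    its <- apriori_frequent_itemsets(transactions, ms)
    derive_rules(its, min_confidence, vocab)
  }
  rules <- mine_at(min_support)
  optimal <- NA_real_
  if (search_optimal_support) {
    ms <- min_support
    last_nonempty <- if (nrow(rules) > 0) min_support else NA_real_
    repeat {
      ms_next <- round(ms + step, 10) # keep the stepped grid exact
      if (ms_next > 1) break
      r <- mine_at(ms_next)
      if (nrow(r) == 0) break
      last_nonempty <- ms_next
      rules <- r
      ms <- ms_next
    }
    optimal <- last_nonempty
  }
  list(rules = rules, transactions = transactions, optimal_support = optimal)
}

#' Behavior-level loneliness associations
#'
#' Discretizes the classifier-selected features into low/moderate/high by
#' equal-frequency binning (on observed values, before any imputation),
#' builds one transaction per participant from the feature bins plus the
#' outcome item, and mines rules whose consequent is the outcome.
#'
#' @param features participants x selected-features numeric matrix (NA =
#'   missing)
#' @param outcome character outcome per participant (e.g. post level or
#'   change category)
#' @param outcome_prefix item prefix for the consequent (e.g. "postlevel")
#' @param min_support,min_confidence thresholds (study values: 0.10, 0.90)
#' @param max_itemset_size cap on the frequent-itemset size (antecedent
#'   plus consequent); Inf = exhaustive
#' @return list: `rules`, `transactions`, `excluded_features` (constant
#'   columns that could not be binned)
#' @export
mine_behavior_associations <- function(features, outcome,
                                       outcome_prefix = "postlevel",
                                       min_support = 0.10,
                                       min_confidence = 0.90,
                                       max_itemset_size = Inf) {
  features <- as.matrix(features)
  stopifnot(nrow(features) == length(outcome))
  if (ncol(features) == 0) {
    return(list(rules = data.table::data.table(
      antecedent = list(), consequent = character(),
      support = numeric(), confidence = numeric()),
      transactions = list(), excluded_features = character()))
  }
  bins <- lapply(seq_len(ncol(features)), function(j)
    discretize_equal_frequency(features[, j]))
  excluded <- colnames(features)[vapply(bins, is.null, logical(1))]
  keep <- which(!vapply(bins, is.null, logical(1)))
  transactions <- lapply(seq_len(nrow(features)), function(i) {
    toks <- vapply(keep, function(j) {
      b <- bins[[j]][i]
      if (is.na(b)) NA_character_ else paste0(colnames(features)[j], "=", b)
    }, character(1))
    c(toks[!is.na(toks)], paste0(outcome_prefix, "=", outcome[i]))
  })
  vocab <- paste0(outcome_prefix, "=", unique(outcome))
  its <- apriori_frequent_itemsets(transactions, min_support,
                                   max_size = max_itemset_size)
  rules <- derive_rules(its, min_confidence, vocab)
  list(rules = rules, transactions = transactions,
       excluded_features = excluded)
}

#' Format association rules as a readable table
#'
#' @param rules data.table from [derive_rules()]
#' @return data.table with antecedent text, consequent, support and
#'   confidence in percent
#' @export
format_rules <- function(rules) {
  data.table::data.table(
    antecedent = vapply(rules$antecedent, paste, character(1), collapse = " & "),
    consequent = rules$consequent,
    support_pct = round(100 * rules$support, 1),
    confidence_pct = round(100 * rules$confidence, 1)
  )
}
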