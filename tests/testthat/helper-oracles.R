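# Independent oracles and small stream builders used across the suite.
# Oracles are deliberately naive (brute force / enumeration) and share no
# code with the implementations they check.

ts_at <- function(...) as.POSIXct(c(...), tz = "UTC")

ts_seq <- function(start, by_s, n) {
  as.POSIXct(start, tz = "UTC") + (seq_len(n) - 1) * by_s
}

# brute-force DBSCAN on a full distance matrix (geosphere distances)
brute_dbscan <- function(lat, lon, eps, min_samples) {
  n <- length(lat)
  if (n == 0) return(integer(0))
  D <- geosphere::distm(cbind(lon, lat))
  nb <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))
  core <- vapply(nb, length, integer(1)) >= min_samples
  labels <- rep(0L, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    queue <- i
    labels[i] <- cl
    qp <- 1L
    while (qp <= length(queue)) {
      j <- queue[qp]; qp <- qp + 1L
      if (!core[j]) next
      for (k in nb[[j]]) {
        if (labels[k] == 0L) {
          labels[k] <- cl
          if (core[k]) queue <- c(queue, k)
        }
      }
    }
  }
  labels[labels == 0L] <- -1L
  labels
}

# label-invariant partition comparison (same noise set, same co-membership)
same_partition <- function(a, b) {
  if (!identical(a == -1L, b == -1L)) return(FALSE)
  ia <- a > 0
  if (!any(ia)) return(TRUE)
  all(outer(a[ia], a[ia], "==") == outer(b[ia], b[ia], "=="))
}

# exhaustive frequent-itemset enumeration (<= ~12 distinct items)
brute_frequent_itemsets <- function(transactions, min_support) {
  items <- sort(unique(unlist(transactions)))
  out <- list()
  for (k in seq_along(items)) {
    for (s in utils::combn(items, k, simplify = FALSE)) {
      supp <- mean(vapply(transactions, function(tr) all(s %in% tr), logical(1)))
      if (supp >= min_support)
        out[[length(out) + 1L]] <- list(items = s, support = supp)
    }
  }
  out
}

itemset_key <- function(items) paste(sort(items), collapse = "|")

# optimal 1-D k-means by exhaustive search over contiguous partitions of the
# sorted scores (the 1-D optimum is always contiguous)
best_1d_partition_sse <- function(x, k) {
  x <- sort(x)
  n <- length(x)
  sse <- function(v) sum((v - mean(v))^2)
  best <- Inf
  cuts <- utils::combn(seq_len(n - 1), k - 1, simplify = FALSE)
  for (ct in cuts) {
    bounds <- c(0, ct, n)
    tot <- sum(vapply(seq_len(k), function(j)
      sse(x[(bounds[j] + 1):bounds[j + 1]]), numeric(1)))
    if (tot < best) best <- tot
  }
  best
}

# direct enumeration of active/sedentary bouts from a 5-min step series
enum_step_bouts <- function(steps, threshold = 10) {
  if (length(steps) == 0) return(list())
  kind <- ifelse(steps >= threshold, "active", "sedentary")
  out <- list()
  cur <- kind[1]; len <- 1L
  for (i in seq_along(kind)[-1]) {
    if (kind[i] == cur) len <- len + 1L
    else { out[[length(out) + 1L]] <- list(kind = cur, n = len); cur <- kind[i]; len <- 1L }
  }
  out[[length(out) + 1L]] <- list(kind = cur, n = len)
  out
}

# small campus fixture and a location stream pinned at a sequence of places
test_campus <- function() default_campus_map()

place_center <- function(map, category) {
  for (p in map$polygons) if (p$category == category)
    return(c(lat = mean(p$coords$lat), lon = mean(p$coords$lon)))
  stop("no such category")
}

# stream of 10-min samples sitting at the given centers (one per sample)
mk_location <- function(start, centers) {
  data.table::data.table(
    timestamp = ts_seq(start, 600, nrow(centers)),
    lat = centers[, 1], lon = centers[, 2])
}

# tiny cached cohort shared by generator-level tests
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_cohort(4, effect_size = 1,
                                calendar = study_calendar("2017-01-18", 2L, 1L),
                                seed = 421L)
    cache
  }
})
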