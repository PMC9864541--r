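#' Discretize a mixed-type dataset into imputation-cell codes
#'
#' Builds the per-row cell key used by fractional hot-deck imputation:
#' categorical variables keep their level codes; continuous variables are
#' cut at observed sample quantiles into `n_bins` ordered codes;
#' semicontinuous variables give their exact zeros a dedicated code and cut
#' the positive part into `n_bins` ordered codes above it. Missing entries
#' stay missing. A variable with fewer distinct observed values than
#' requested bins gets fewer bins (logged in the result).
#'
#' @param data Incomplete tibble.
#' @param schema Optional schema.
#' @param n_bins Number of quantile bins for continuous variables.
#' @return List with `codes` (integer matrix, `NA` = missing), `ordered`
#'   (logical per variable: codes have a neighbor order), and `bin_notes`
#'   (variables whose bin count was reduced).
#' @export
fhd_discretize <- function(data, schema = NULL, n_bins = 3) {
  stopifnot(n_bins >= 2)
  schema <- get_schema(data, schema)
  n <- nrow(data)
  codes <- matrix(NA_integer_, n, nrow(schema),
                  dimnames = list(NULL, schema$name))
  ordered <- logical(nrow(schema))
  names(ordered) <- schema$name
  notes <- character(0)

  quantile_codes <- function(x, k) {
    obs <- x[!is.na(x)]
    br <- unique(quantile(obs, probs = seq_len(k - 1) / k, names = FALSE))
    out <- rep(NA_integer_, length(x))
    out[!is.na(x)] <- findInterval(x[!is.na(x)], br, left.open = TRUE) + 1L
    got <- length(unique(out[!is.na(out)]))
    list(codes = out, reduced = got < k)
  }

  for (j in seq_len(nrow(schema))) {
    v <- schema[j, ]
    x <- data[[v$name]]
    if (is_categorical(v$vtype)) {
      codes[, j] <- as.integer(x)
      ordered[j] <- v$vtype != "nominal"
    } else if (v$vtype == "semicontinuous") {
      out <- rep(NA_integer_, n)
      zero <- !is.na(x) & x == 0
      pos <- !is.na(x) & x > 0
      out[zero] <- 1L
      if (any(pos)) {
        qc <- quantile_codes(ifelse(pos, x, NA), n_bins)
        out[pos] <- qc$codes[pos] + 1L
        if (qc$reduced) notes <- c(notes, v$name)
      }
      codes[, j] <- out
      ordered[j] <- TRUE
    } else {
      qc <- quantile_codes(x, n_bins)
      codes[, j] <- qc$codes
      if (qc$reduced) notes <- c(notes, v$name)
      ordered[j] <- TRUE
    }
  }
  list(codes = codes, ordered = ordered, bin_notes = notes)
}

# Eligible-donor count per recipient: donors agreeing with the recipient on
# every observed entry of its cell key. Recipients sharing a key pattern
# are counted once.
eligible_counts <- function(codes, donor_rows, recip_rows) {
  D <- codes[donor_rows, , drop = FALSE]
  keys <- apply(codes[recip_rows, , drop = FALSE], 1, paste, collapse = "|")
  uk <- !duplicated(keys)
  counts_u <- vapply(which(uk), function(i) {
    r <- codes[recip_rows[i], ]
    o <- which(!is.na(r))
    if (!length(o)) return(length(donor_rows))
    sum(rowSums(D[, o, drop = FALSE] ==
                  matrix(r[o], nrow(D), length(o), byrow = TRUE)) == length(o))
  }, numeric(1))
  counts_u[match(keys, keys[uk])]
}

# Per-variable donor x recipient match matrix: TRUE when the donor agrees
# with the recipient on that variable's code or the recipient has it
# missing. A recipient is eligible for a donor when all variables match,
# i.e. when the column sum of matches equals the variable count — which
# lets candidate merges be scored by updating a single variable's matrix.
match_matrix <- function(dcol, rcol) {
  m <- outer(dcol, rcol, `==`)
  m[, is.na(rcol)] <- TRUE
  m
}

apply_code_maps <- function(codes, maps) {
  for (v in names(maps)) {
    m <- maps[[v]]
    codes[, v] <- m[as.character(codes[, v])]
  }
  codes
}

#' Collapse imputation cells until every recipient has enough donors
#'
#' While some recipient has fewer than `M` eligible donors, coarsens the
#' discretization one merge at a time: candidate merges are every adjacent
#' code pair of an ordered variable and the two smallest-frequency codes of
#' a nominal variable; the merge that maximizes the minimum eligible-donor
#' count across recipients is applied (first candidate on ties). Full
#' collapse of every variable leaves a single universal cell, so the loop
#' always terminates. If the whole dataset has fewer than `M` complete
#' rows, `M` is reduced to that number.
#'
#' @param disc Result of [fhd_discretize()].
#' @param M Required donors per recipient.
#' @return List with the merged `codes`, the effective `M`, the merge log,
#'   and the donor/recipient row indices.
#' @export
fhd_collapse <- function(disc, M = 5) {
  stopifnot(M >= 1)
  codes <- disc$codes
  ordered <- disc$ordered
  donor_rows <- which(stats::complete.cases(codes))
  recip_rows <- which(!stats::complete.cases(codes))
  if (length(donor_rows) < M) {
    warn(sprintf("only %d complete rows; donor count reduced from %d",
                 length(donor_rows), M))
    M <- max(length(donor_rows), 1L)
  }
  merges <- list()
  if (!length(recip_rows)) {
    return(list(codes = codes, M = M, merges = merges,
                donor_rows = donor_rows, recip_rows = recip_rows))
  }
  p <- ncol(codes)
  # deduplicate recipients by cell key: equal keys have equal donor counts
  keys <- apply(codes[recip_rows, , drop = FALSE], 1, paste, collapse = "|")
  urep <- recip_rows[!duplicated(keys)]
  # per-variable match matrices and their running sum; a recipient class is
  # eligible for a donor exactly when the sum equals p
  mm <- lapply(colnames(codes), function(v) {
    match_matrix(codes[donor_rows, v], codes[urep, v])
  })
  names(mm) <- colnames(codes)
  msum <- Reduce(`+`, mm)
  counts_from <- function(s) .colSums(s == p, length(donor_rows), length(urep))
  repeat {
    counts <- counts_from(msum)
    if (min(counts) >= M) break
    cands <- list()
    for (v in colnames(codes)) {
      cv <- sort(unique(codes[, v][!is.na(codes[, v])]))
      if (length(cv) < 2) next
      if (ordered[v]) {
        for (i in seq_len(length(cv) - 1)) {
          cands[[length(cands) + 1]] <- list(var = v, from = cv[i + 1],
                                             to = cv[i])
        }
      } else {
        freq <- table(codes[, v])
        small <- as.integer(names(sort(freq)))[1:2]
        cands[[length(cands) + 1]] <- list(var = v, from = max(small),
                                           to = min(small))
      }
    }
    if (!length(cands)) break # universal cell reached
    trial <- purrr::map(cands, function(cd) {
      col <- codes[, cd$var]
      col[!is.na(col) & col == cd$from] <- cd$to
      mv <- match_matrix(col[donor_rows], col[urep])
      list(col = col, mv = mv,
           score = min(counts_from(msum - mm[[cd$var]] + mv)))
    })
    ibest <- which.max(purrr::map_dbl(trial, "score"))
    best <- cands[[ibest]]
    codes[, best$var] <- trial[[ibest]]$col
    msum <- msum - mm[[best$var]] + trial[[ibest]]$mv
    mm[[best$var]] <- trial[[ibest]]$mv
    merges[[length(merges) + 1]] <- tibble::tibble(
      variable = best$var, from = best$from, into = best$to,
      min_donors_after = trial[[ibest]]$score
    )
  }
  list(codes = codes, M = M, merges = dplyr::bind_rows(merges),
       donor_rows = donor_rows, recip_rows = recip_rows)
}

#' Fractional hot-deck imputation
#'
#' The fractional hot-deck comparator: the data are discretized into
#' imputation cells ([fhd_discretize()]), cells are collapsed automatically
#' until every recipient (row with at least one missing value) has at least
#' `donors` eligible donors ([fhd_collapse()]), and each recipient then
#' receives `donors` distinct donor rows drawn uniformly without
#' replacement from its cell, each carrying fractional weight `1/donors`.
#' All of a recipient's missing variables are imputed jointly from the same
#' donor row within each fractional record, preserving the donors' observed
#' joint distribution.
#'
#' No variance estimation is performed; downstream precision comes from the
#' Monte-Carlo evaluation layer.
#'
#' @param data Incomplete tibble.
#' @param schema Optional schema.
#' @param donors Donors per recipient (default 5).
#' @param n_bins Quantile bins for continuous variables (default 3).
#' @param seed Integer seed.
#' @return An [new_imputation_result()] of kind `"fractional"` whose
#'   `assignment` has one row per (recipient, fractional record):
#'   `recipient`, `record`, `donor`, `weight`.
#' @examples
#' pop <- generate_population(brfss_like_spec(), n = 300, seed = 3)
#' amp <- ampute(pop, "MAR", seed = 3)
#' res <- impute_fhd(amp$data, donors = 5, seed = 3)
#' res
#' @export
impute_fhd <- function(data, schema = NULL, donors = 5, n_bins = 3,
                       seed = NULL) {
  schema <- get_schema(data, schema)
  disc <- fhd_discretize(data, schema, n_bins)
  coll <- fhd_collapse(disc, M = donors)
  M <- coll$M
  D <- coll$codes[coll$donor_rows, , drop = FALSE]
  keys <- apply(coll$codes[coll$recip_rows, , drop = FALSE], 1,
                paste, collapse = "|")
  elig_by_key <- purrr::map(
    setNames(which(!duplicated(keys)), keys[!duplicated(keys)]),
    function(i) {
      key <- coll$codes[coll$recip_rows[i], ]
      o <- which(!is.na(key))
      if (!length(o)) return(coll$donor_rows)
      coll$donor_rows[rowSums(D[, o, drop = FALSE] ==
                                matrix(key[o], nrow(D), length(o),
                                       byrow = TRUE)) == length(o)]
    }
  )
  assignment <- with_seed_maybe(seed, {
    sel_list <- lapply(seq_along(coll$recip_rows), function(i) {
      elig <- elig_by_key[[keys[i]]]
      take <- min(M, length(elig))
      if (length(elig) > take) sample(elig, take) else elig
    })
    sizes <- lengths(sel_list)
    tibble::tibble(
      recipient = rep(coll$recip_rows, sizes),
      record = unlist(lapply(sizes, seq_len)),
      donor = unlist(sel_list),
      weight = rep(1 / sizes, sizes)
    )
  })
  new_imputation_result(
    "fractional", method = "fhd", data = data, assignment = assignment,
    diagnostics = list(
      cells_collapsed = if (is.data.frame(coll$merges)) nrow(coll$merges) else 0L,
      merges = coll$merges, M = M, bin_notes = disc$bin_notes
    )
  )
}

#' Expand a fractional imputation into a weighted analysis dataset
#'
#' Complete rows enter once with weight 1; each recipient enters once per
#' fractional record with its missing variables copied jointly from that
#' record's donor row and the record's fractional weight attached.
#'
#' @param result A fractional [new_imputation_result()].
#' @return Tibble: original columns plus `.weight` and `.source_row`.
#' @export
fractional_expand <- function(result) {
  stopifnot(result$kind == "fractional")
  data <- result$data
  asg <- result$assignment
  complete_rows <- setdiff(seq_len(nrow(data)), unique(asg$recipient))
  base <- data[complete_rows, , drop = FALSE]
  base$.weight <- 1
  base$.source_row <- complete_rows
  recs <- data[asg$recipient, , drop = FALSE]
  for (v in names(data)) {
    mis <- is.na(recs[[v]])
    if (any(mis)) {
      recs[[v]][mis] <- data[[v]][asg$donor[mis]]
    }
  }
  recs$.weight <- asg$weight
  recs$.source_row <- asg$recipient
  out <- dplyr::bind_rows(base, recs)
  attr(out, "schema") <- attr(data, "schema")
  out
}
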