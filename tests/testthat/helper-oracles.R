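# Independent reference implementations used as oracles. These deliberately
# avoid the package's internal code paths: plain loops, direct products,
# explicit pair counting.

# small random schema + case base for property tests -------------------------
toy_schema <- function(n_internal = 3, kinds = c("numeric", "ordinal", "binary")) {
  specs <- list(feature_spec("id", "categorical", channel = "id"))
  for (i in seq_len(n_internal)) {
    kind <- kinds[((i - 1) %% length(kinds)) + 1]
    specs <- c(specs, list(switch(kind,
      numeric = feature_spec(paste0("f", i), "numeric", 0, 10,
                             weight = sample(1:3, 1)),
      ordinal = feature_spec(paste0("f", i), "ordinal", 1, 5,
                             weight = sample(1:3, 1)),
      binary = feature_spec(paste0("f", i), "binary", weight = sample(1:3, 1))
    )))
  }
  specs <- c(specs, list(feature_spec("class", "binary", channel = "label")))
  do.call(feature_schema, specs)
}

toy_casebase <- function(schema, n) {
  out <- tibble::tibble(id = sprintf("c%03d", seq_len(n)))
  for (i in seq_len(nrow(schema))) {
    sp <- schema[i, ]
    if (sp$channel == "id") next
    out[[sp$name]] <- if (sp$kind == "binary") {
      sample(0:1, n, replace = TRUE)
    } else if (sp$kind == "ordinal") {
      sample(seq(sp$lower, sp$upper), n, replace = TRUE)
    } else {
      round(runif(n, sp$lower, sp$upper), 3)
    }
  }
  # ensure both classes present
  if (n >= 2 && length(unique(out$class)) < 2) out$class[1:2] <- c(0, 1)
  out
}

# naive Bayes posterior by direct multiplication (no log space) ---------------
nb_posterior_direct <- function(model, case) {
  joint <- c("0" = model$priors[["0"]], "1" = model$priors[["1"]])
  for (f in model$features) {
    cond <- model$conditionals[[f]]
    for (cl in c("0", "1")) {
      lik <- if (cond$type == "gaussian") {
        p <- cond$params[[cl]]
        1 / sqrt(2 * pi * p$var) * exp(-(as.numeric(case[[f]]) - p$mean)^2 / (2 * p$var))
      } else {
        v <- as.character(case[[f]])
        if (v %in% names(cond$table[[cl]])) cond$table[[cl]][[v]]
        else cond$alpha / (cond$n_class[[cl]] + cond$alpha * length(cond$levels))
      }
      joint[[cl]] <- joint[[cl]] * lik
    }
  }
  joint / sum(joint)
}

# retrieval by brute-force per-feature loops ----------------------------------
brute_similarity <- function(query, stored, schema) {
  num <- 0; den <- 0
  for (i in seq_len(nrow(schema))) {
    sp <- schema[i, ]
    if (sp$channel != "internal") next
    s <- if (sp$kind %in% c("numeric", "ordinal")) {
      1 - abs(as.numeric(query[[sp$name]]) - as.numeric(stored[[sp$name]])) /
        (sp$upper - sp$lower)
    } else {
      if (as.character(query[[sp$name]]) == as.character(stored[[sp$name]])) 1 else 0
    }
    num <- num + sp$weight * s
    den <- den + sp$weight
  }
  num / den
}

brute_retrieve <- function(base, query, schema, k) {
  sims <- vapply(seq_len(nrow(base)), function(i) {
    brute_similarity(query, base[i, ], schema)
  }, numeric(1))
  ord <- order(-sims, as.character(base$id))
  keep <- ord[seq_len(min(k, nrow(base)))]
  tibble::tibble(case_id = as.character(base$id)[keep], similarity = sims[keep],
                 rank = seq_along(keep))
}

# Kendall's W by explicit counting and summation -------------------------------
midrank_loop <- function(x) {
  vapply(seq_along(x), function(i) {
    sum(x < x[i]) + (sum(x == x[i]) + 1) / 2
  }, numeric(1))
}

kendalls_w_direct <- function(scores) {
  m <- nrow(scores); n <- ncol(scores)
  ranks <- matrix(0, m, n)
  for (i in seq_len(m)) ranks[i, ] <- midrank_loop(scores[i, ])
  S <- 0
  for (j in seq_len(n)) {
    Rj <- sum(ranks[, j])
    S <- S + (Rj - m * (n + 1) / 2)^2
  }
  Tsum <- 0
  for (i in seq_len(m)) {
    for (v in unique(scores[i, ])) {
      t <- sum(scores[i, ] == v)
      Tsum <- Tsum + t^3 - t
    }
  }
  12 * S / (m^2 * (n^3 - n) - m * Tsum)
}

# AUC by Mann-Whitney pair counting --------------------------------------------
auc_pairs <- function(scores, truth) {
  pos <- scores[truth == 1]; neg <- scores[truth == 0]
  total <- 0
  for (a in pos) for (b in neg) {
    total <- total + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}
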