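#' Load a packaged DVMSQ model parameter set
#'
#' The package ships the final 17-item bifactor graded response model
#' parameters for two calibration samples: a general-population crowdsourced
#' sample (`prolific_table5`) and a sample of autistic adults
#' (`spark_table5`). Both assume orthogonal standard-normal latent variables:
#' one general misophonia factor and four specific factors (anger/aggression,
#' distress/avoidance, overall impairment, global impact).
#'
#' @param name `"prolific_table5"` or `"spark_table5"`, or a path to a YAML
#'   model file in the same format.
#' @return A [bifactor_grm()] object.
#' @export
#' @examples
#' m <- load_model_fixture("prolific_table5")
#' m$a["item8", ]
load_model_fixture <- function(name = c("prolific_table5", "spark_table5")) {
  if (file.exists(name[1])) {
    path <- name[1]
  } else {
    name <- match.arg(name)
    path <- system.file("extdata", paste0(name, ".yaml"), package = "dvmsq")
    if (path == "") abort(sprintf("Fixture %s not found.", name))
  }
  obj <- yaml::read_yaml(path)
  items <- vapply(obj$items, function(x) as.integer(x$item_id), integer(1))
  a <- t(vapply(obj$items, function(x) as.numeric(x$a),
                numeric(length(obj$factors))))
  d <- t(vapply(obj$items, function(x) as.numeric(x$d), numeric(4)))
  if (!is.null(obj$checksum)) {
    got <- round(sum(abs(cbind(a, d))), 6)
    if (abs(got - obj$checksum) > 1e-6) {
      abort(sprintf("Corrupted model fixture %s: checksum %s, expected %s.",
                    path, got, obj$checksum))
    }
  }
  bifactor_grm(a, d, factors = obj$factors, items = items)
}

#' @rdname load_model_fixture
#' @param sample `"prolific"` or `"spark"`.
#' @export
dvmsq_model <- function(sample = c("prolific", "spark")) {
  sample <- match.arg(sample)
  load_model_fixture(paste0(sample, "_table5"))
}
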