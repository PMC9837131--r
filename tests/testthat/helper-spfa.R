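# shared helpers: parameter flattening for gradient checks, tiny fixtures

flatten_pars <- function(pars) unlist(pars, use.names = FALSE)

unflatten_pars <- function(v, template) {
  out <- template
  pos <- 1L
  for (nm in names(template)) {
    n <- length(template[[nm]])
    vals <- v[pos:(pos + n - 1L)]
    out[[nm]] <- if (is.null(dim(template[[nm]]))) as.vector(vals)
                 else array(vals, dim = dim(template[[nm]]))
    pos <- pos + n
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# central finite differences of f at v
fd_gradient <- function(f, v, h = 1e-5) {
  vapply(seq_along(v), function(i) {
    vp <- v; vm <- v
    vp[i] <- vp[i] + h; vm[i] <- vm[i] - h
    (f(vp) - f(vm)) / (2 * h)
  }, 0)
}

# a tiny deterministic event table for cohort tests
tiny_events <- function() {
  d <- function(x) as.Date(x)
  data.frame(
    patient_id = c("A", "A", "A", "A", "A",
                   "B", "B", "B",
                   "C", "C"),
    date = d(c("2020-01-01", "2020-02-01", "2020-03-01", "2020-03-10",
               "2020-03-20",
               "2020-01-05", "2020-02-10", "2020-05-01",
               "2020-01-15", "2020-02-20")),
    code_system = c("demographic", "diagnosis", "drug", "diagnosis",
                    "diagnosis",
                    "demographic", "drug", "diagnosis",
                    "demographic", "diagnosis"),
    code = c("age:77", "DX1", "RXT", "DX2", "DX1",
             "age:80", "RXT", "DX1",
             "age:65", "DX2"),
    hospitalization_flag = c(FALSE, FALSE, FALSE, TRUE, FALSE,
                             FALSE, FALSE, TRUE,
                             FALSE, FALSE),
    death_flag = FALSE,
    stringsAsFactors = FALSE
  )
}
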