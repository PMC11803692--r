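#include <Rcpp.h>
#include <R_ext/RS.h>
using namespace Rcpp;

// LAPACK banded complex solver; the discretized Helmholtz operator is
// assembled in banded storage with a slice-fastest ordering so its
// bandwidth stays at (number of slices) x (rows), which keeps the direct
// factorization at desk scale.
extern "C" {
  void F77_NAME(zgbsv)(const int* n, const int* kl, const int* ku,
                       const int* nrhs, Rcomplex* ab, const int* ldab,
                       int* ipiv, Rcomplex* b, const int* ldb, int* info);
}

// [[Rcpp::export(name = ".zgbsv_solve")]]
ComplexVector zgbsv_solve(ComplexMatrix ab, int kl, int ku, ComplexVector b) {
  int n = ab.ncol();
  int ldab = ab.nrow();
  if (ldab != 2 * kl + ku + 1)
    stop("banded storage must have 2*kl + ku + 1 rows");
  if (b.size() != n) stop("right-hand side length mismatch");
  int nrhs = 1, info = 0;
  std::vector<int> ipiv(n);
  ComplexMatrix abc = clone(ab);
  ComplexVector x = clone(b);
  F77_CALL(zgbsv)(&n, &kl, &ku, &nrhs, abc.begin(), &ldab, ipiv.data(),
                  x.begin(), &n, &info);
  if (info != 0) stop("zgbsv failed with info = %d (singular system)", info);
  return x;
}
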