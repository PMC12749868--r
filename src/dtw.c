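#include <R.h>
#include <Rinternals.h>
#include <float.h>

/* Dynamic time warping with absolute-difference local cost.
 * Full (unconstrained) alignment; returns total optimal cost and the
 * number of steps on one optimal path so callers can normalize by
 * path length.  Ties broken diagonal > left > down, matching the
 * backtracking order below. */
SEXP C_dtw(SEXP a_, SEXP b_)
{
    const double *a = REAL(a_);
    const double *b = REAL(b_);
    const int n = LENGTH(a_);
    const int m = LENGTH(b_);
    if (n == 0 || m == 0)
        error("dtw: empty input");

    double *D = (double *) R_alloc((size_t) n * m, sizeof(double));
#define AT(i, j) ((size_t)(i) + (size_t)(j) * n)

    for (int j = 0; j < m; j++) {
        for (int i = 0; i < n; i++) {
            double c = fabs(a[i] - b[j]);
            double best;
            if (i == 0 && j == 0)
                best = 0.0;
            else if (i == 0)
                best = D[AT(0, j - 1)];
            else if (j == 0)
                best = D[AT(i - 1, 0)];
            else {
                best = D[AT(i - 1, j - 1)];
                if (D[AT(i - 1, j)] < best) best = D[AT(i - 1, j)];
                if (D[AT(i, j - 1)] < best) best = D[AT(i, j - 1)];
            }
            D[AT(i, j)] = c + best;
        }
    }

    /* backtrack to count path steps */
    int i = n - 1, j = m - 1, steps = 1;
    while (i > 0 || j > 0) {
        if (i == 0) {
            j--;
        } else if (j == 0) {
            i--;
        } else {
            double d = D[AT(i - 1, j - 1)];
            double l = D[AT(i, j - 1)];
            double u = D[AT(i - 1, j)];
            if (d <= l && d <= u) { i--; j--; }
            else if (l <= u)      { j--; }
            else                  { i--; }
        }
        steps++;
    }

    SEXP out = PROTECT(allocVector(REALSXP, 2));
    REAL(out)[0] = D[AT(n - 1, m - 1)];
    REAL(out)[1] = (double) steps;
    UNPROTECT(1);
    return out;
#undef AT
}
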