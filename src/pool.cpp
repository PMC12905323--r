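#include <Rcpp.h>
using namespace Rcpp;

// Max-pool a stack of binary 3D channels by an integer factor.
// x holds nchan channels of dims[0]*dims[1]*dims[2] cells each
// (column-major, channel-contiguous); output is channel-contiguous
// pooled cells (binary max = logical OR over each block).

// [[Rcpp::export]]
NumericVector pool_stack_cpp(IntegerVector x, int nchan,
                             IntegerVector dims, int f) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int mx = nx / f, my = ny / f, mz = nz / f;
  const int cell_in = nx * ny * nz, cell_out = mx * my * mz;
  NumericVector out(nchan * cell_out);
  for (int c = 0; c < nchan; ++c) {
    const int in0 = c * cell_in, out0 = c * cell_out;
    for (int k = 0; k < nz; ++k) {
      const int ko = k / f;
      for (int j = 0; j < ny; ++j) {
        const int jo = j / f;
        const int inrow = in0 + nx * (j + ny * k);
        const int outrow = out0 + mx * (jo + my * ko);
        for (int i = 0; i < nx; ++i) {
          if (x[inrow + i]) out[outrow + i / f] = 1.0;
        }
      }
    }
  }
  return out;
}
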