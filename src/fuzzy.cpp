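#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Stack-machine evaluation of fuzzified Boolean rules.
// Program: integer matrix with rows (op, arg):
//   op 0 = push variable arg (0-based node index)
//   op 1 = push constant arg (0 or 1)
//   op 2 = NOT (1 - top)
//   op 3 = AND (min or product)
//   op 4 = OR  (max or probabilistic sum)
// semantics: 0 = minmax, 1 = probabilistic.

// [[Rcpp::export]]
NumericVector cpp_eval_fuzzy(List programs, NumericVector x, int semantics) {
  const int n = programs.size();
  NumericVector out(n);
  std::vector<double> stack;
  stack.reserve(32);
  for (int i = 0; i < n; ++i) {
    IntegerMatrix prog = programs[i];
    stack.clear();
    for (int r = 0; r < prog.nrow(); ++r) {
      const int op = prog(r, 0), arg = prog(r, 1);
      switch (op) {
      case 0: stack.push_back(x[arg]); break;
      case 1: stack.push_back((double)arg); break;
      case 2: stack.back() = 1.0 - stack.back(); break;
      case 3: {
        double b = stack.back(); stack.pop_back();
        double &a = stack.back();
        a = semantics == 0 ? std::min(a, b) : a * b;
        break;
      }
      case 4: {
        double b = stack.back(); stack.pop_back();
        double &a = stack.back();
        a = semantics == 0 ? std::max(a, b) : a + b - a * b;
        break;
      }
      }
    }
    out[i] = stack.back();
  }
  return out;
}
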