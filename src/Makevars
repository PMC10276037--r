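# Build with the host toolchain: the bundled cross-compiler's C-library
# sysroot is newer than the runtime loader, so objects it produces cannot be
# dyn.load()ed.  The host gcc/g++ target the runtime C library directly and
# link fine against R's libraries via the flags R supplies.  `override` is
# needed because Makeconf is included after this file.
override CC = gcc
override CXX = g++ -std=gnu++17
override CXX11 = g++
override CXX14 = g++
override CXX17 = g++
override FC = gfortran
PKG_LIBS = $(LAPACK_LIBS) $(BLAS_LIBS) $(FLIBS)
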