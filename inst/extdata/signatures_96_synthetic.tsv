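## synthetic 96-channel reference signatures (pyrimidine convention)
## constructed stand-ins with the qualitative channel preferences of
## aging/clock (AC1: C>T at NpCpG), homologous-recombination deficiency
## (AC3: near-flat), mismatch-repair deficiency (AC6: C>T at GpCpN plus
## T>C), UV exposure (AC7: C>T at dipyrimidines), and a flat background.
## NOT copies of any signature database.
#channel	AC1	AC3	AC6	AC7	FLAT
A[C>A]A	0.00115741	0.00868056	0.00096525	0.00091912	0.01041635
A[C>A]C	0.00115741	0.00868056	0.00096525	0.00091912	0.01041667
A[C>A]G	0.00115741	0.00868056	0.00096525	0.00091912	0.01041667
A[C>A]T	0.00115741	0.00868056	0.00096525	0.00091912	0.01041667
C[C>A]A	0.00115741	0.00868056	0.00096525	0.00091912	0.01041667
C[C>A]C	0.00115741	0.00868056	0.00096525	0.00091912	0.01041667
C[C>A]G	0.00115741	0.00868056	0.00096525	0.00091912	0.01041667
C[C>A]T	0.00115741	0.00868056	0.00096525	0.00091912	0.01041667
G[C>A]A	0.00115741	0.00868056	0.00096525	0.00091912	0.01041667
G[C>A]C	0.00115741	0.00868056	0.00096525	0.00091912	0.01041667
G[C>A]G	0.00115741	0.00868056	0.00096525	0.00091912	0.01041667
G[C>A]T	0.00115741	0.00868056	0.00096525	0.00091912	0.01041667
T[C>A]A	0.00115741	0.00868056	0.00096525	0.00091912	0.01041667
T[C>A]C	0.00115741	0.00868056	0.00096525	0.00091912	0.01041667
T[C>A]G	0.00115741	0.00868056	0.00096525	0.00091912	0.01041667
T[C>A]T	0.00115741	0.00868056	0.00096525	0.00091912	0.01041667
A[C>G]A	0.00115741	0.01388857	0.00096525	0.00091912	0.01041667
A[C>G]C	0.00115741	0.01388889	0.00096525	0.00091912	0.01041667
A[C>G]G	0.00115741	0.01388889	0.00096525	0.00091912	0.01041667
A[C>G]T	0.00115741	0.01388889	0.00096525	0.00091912	0.01041667
C[C>G]A	0.00115741	0.01388889	0.00096525	0.00091912	0.01041667
C[C>G]C	0.00115741	0.01388889	0.00096525	0.00091912	0.01041667
C[C>G]G	0.00115741	0.01388889	0.00096525	0.00091912	0.01041667
C[C>G]T	0.00115741	0.01388889	0.00096525	0.00091912	0.01041667
G[C>G]A	0.00115741	0.01388889	0.00096525	0.00091912	0.01041667
G[C>G]C	0.00115741	0.01388889	0.00096525	0.00091912	0.01041667
G[C>G]G	0.00115741	0.01388889	0.00096525	0.00091912	0.01041667
G[C>G]T	0.00115741	0.01388889	0.00096525	0.00091912	0.01041667
T[C>G]A	0.00115741	0.01388889	0.00096525	0.00091912	0.01041667
T[C>G]C	0.00115741	0.01388889	0.00096525	0.00091912	0.01041667
T[C>G]G	0.00115741	0.01388889	0.00096525	0.00091912	0.01041667
T[C>G]T	0.00115741	0.01388889	0.00096525	0.00091912	0.01041667
A[C>T]A	0.01388889	0.00868056	0.00096525	0.00091912	0.01041667
A[C>T]C	0.01388889	0.00868056	0.00096525	0.00091912	0.01041667
A[C>T]G	0.18518495	0.00868056	0.00096525	0.00091912	0.01041667
A[C>T]T	0.01388889	0.00868056	0.00096525	0.00091912	0.01041667
C[C>T]A	0.01388889	0.00868056	0.00096525	0.11488947	0.01041667
C[C>T]C	0.01388889	0.00868056	0.00096525	0.11488971	0.01041667
C[C>T]G	0.18518519	0.00868056	0.00096525	0.11488971	0.01041667
C[C>T]T	0.01388889	0.00868056	0.00096525	0.11488971	0.01041667
G[C>T]A	0.01388889	0.00868056	0.07722012	0.00091912	0.01041667
G[C>T]C	0.01388889	0.00868056	0.07722008	0.00091912	0.01041667
G[C>T]G	0.18518519	0.00868056	0.07722008	0.00091912	0.01041667
G[C>T]T	0.01388889	0.00868056	0.07722008	0.00091912	0.01041667
T[C>T]A	0.01388889	0.00868056	0.00096525	0.11488971	0.01041667
T[C>T]C	0.01388889	0.00868056	0.00096525	0.11488971	0.01041667
T[C>T]G	0.18518519	0.00868056	0.00096525	0.11488971	0.01041667
T[C>T]T	0.01388889	0.00868056	0.00096525	0.11488971	0.01041667
A[T>A]A	0.00115741	0.01388889	0.00096525	0.00091912	0.01041667
A[T>A]C	0.00115741	0.01388889	0.00096525	0.00091912	0.01041667
A[T>A]G	0.00115741	0.01388889	0.00096525	0.00091912	0.01041667
A[T>A]T	0.00115741	0.01388889	0.00096525	0.00091912	0.01041667
C[T>A]A	0.00115741	0.01388889	0.00096525	0.00091912	0.01041667
C[T>A]C	0.00115741	0.01388889	0.00096525	0.00091912	0.01041667
C[T>A]G	0.00115741	0.01388889	0.00096525	0.00091912	0.01041667
C[T>A]T	0.00115741	0.01388889	0.00096525	0.00091912	0.01041667
G[T>A]A	0.00115741	0.01388889	0.00096525	0.00091912	0.01041667
G[T>A]C	0.00115741	0.01388889	0.00096525	0.00091912	0.01041667
G[T>A]G	0.00115741	0.01388889	0.00096525	0.00091912	0.01041667
G[T>A]T	0.00115741	0.01388889	0.00096525	0.00091912	0.01041667
T[T>A]A	0.00115741	0.01388889	0.00096525	0.00091912	0.01041667
T[T>A]C	0.00115741	0.01388889	0.00096525	0.00091912	0.01041667
T[T>A]G	0.00115741	0.01388889	0.00096525	0.00091912	0.01041667
T[T>A]T	0.00115741	0.01388889	0.00096525	0.00091912	0.01041667
A[T>C]A	0.00115741	0.00868056	0.03861004	0.00091912	0.01041667
A[T>C]C	0.00115741	0.00868056	0.03861004	0.00091912	0.01041667
A[T>C]G	0.00115741	0.00868056	0.03861004	0.00091912	0.01041667
A[T>C]T	0.00115741	0.00868056	0.03861004	0.00091912	0.01041667
C[T>C]A	0.00115741	0.00868056	0.03861004	0.00091912	0.01041667
C[T>C]C	0.00115741	0.00868056	0.03861004	0.00091912	0.01041667
C[T>C]G	0.00115741	0.00868056	0.03861004	0.00091912	0.01041667
C[T>C]T	0.00115741	0.00868056	0.03861004	0.00091912	0.01041667
G[T>C]A	0.00115741	0.00868056	0.03861004	0.00091912	0.01041667
G[T>C]C	0.00115741	0.00868056	0.03861004	0.00091912	0.01041667
G[T>C]G	0.00115741	0.00868056	0.03861004	0.00091912	0.01041667
G[T>C]T	0.00115741	0.00868056	0.03861004	0.00091912	0.01041667
T[T>C]A	0.00115741	0.00868056	0.03861004	0.00091912	0.01041667
T[T>C]C	0.00115741	0.00868056	0.03861004	0.00091912	0.01041667
T[T>C]G	0.00115741	0.00868056	0.03861004	0.00091912	0.01041667
T[T>C]T	0.00115741	0.00868056	0.03861004	0.00091912	0.01041667
A[T>G]A	0.00115741	0.00868056	0.00096525	0.00091912	0.01041667
A[T>G]C	0.00115741	0.00868056	0.00096525	0.00091912	0.01041667
A[T>G]G	0.00115741	0.00868056	0.00096525	0.00091912	0.01041667
A[T>G]T	0.00115741	0.00868056	0.00096525	0.00091912	0.01041667
C[T>G]A	0.00115741	0.00868056	0.00096525	0.00091912	0.01041667
C[T>G]C	0.00115741	0.00868056	0.00096525	0.00091912	0.01041667
C[T>G]G	0.00115741	0.00868056	0.00096525	0.00091912	0.01041667
C[T>G]T	0.00115741	0.00868056	0.00096525	0.00091912	0.01041667
G[T>G]A	0.00115741	0.00868056	0.00096525	0.00091912	0.01041667
G[T>G]C	0.00115741	0.00868056	0.00096525	0.00091912	0.01041667
G[T>G]G	0.00115741	0.00868056	0.00096525	0.00091912	0.01041667
G[T>G]T	0.00115741	0.00868056	0.00096525	0.00091912	0.01041667
T[T>G]A	0.00115741	0.00868056	0.00096525	0.00091912	0.01041667
T[T>G]C	0.00115741	0.00868056	0.00096525	0.00091912	0.01041667
T[T>G]G	0.00115741	0.00868056	0.00096525	0.00091912	0.01041667
T[T>G]T	0.00115741	0.00868056	0.00096525	0.00091912	0.01041667
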