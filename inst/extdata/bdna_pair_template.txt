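# Idealized B-form DNA Watson-Crick base-pair template
# Source: Arnott fiber-diffraction B-DNA geometry (generated with
# AmberTools nab fd_helix('abdna'), heavy atoms of the central
# base pair of a 3-bp homopolymer duplex; synthetic idealized
# coordinates, not experimental data).
# Frame: origin on helix axis at mean C1' height; z = helix axis;
# y = in-plane C1'(strand A) -> C1'(strand B). Units: nm.
# rise_nm = 0.338000
# twist_deg = 35.999841
pair strand resname atom element x y z
A A DA P P -0.065787 -0.894858 -0.214100
A A DA OP1 O -0.005067 -1.029215 -0.200000
A A DA OP2 O -0.189313 -0.871604 -0.135900
A A DA O5' O 0.042587 -0.782625 -0.178800
A A DA C5' C 0.144320 -0.750982 -0.275600
A A DA C4' C 0.269433 -0.701963 -0.205300
A A DA O4' O 0.247648 -0.563017 -0.182300
A A DA C1' C 0.230777 -0.533329 -0.045200
A A DA N9 N 0.109834 -0.446809 -0.037000
A A DA C8 C -0.022953 -0.483083 -0.038500
A A DA N7 N -0.104957 -0.382952 -0.029600
A A DA C5 C -0.021925 -0.272083 -0.021700
A A DA C6 C -0.048268 -0.134646 -0.010500
A A DA N6 N -0.171961 -0.083212 -0.005100
A A DA N1 N 0.057567 -0.051595 -0.005100
A A DA C2 C 0.180164 -0.103346 -0.010500
A A DA N3 N 0.216773 -0.229206 -0.020900
A A DA C4 C 0.109025 -0.310126 -0.026200
A A DA C3' C 0.294984 -0.760704 -0.066500
A A DA C2' C 0.214792 -0.667946 0.024700
A A DA O3' O 0.432386 -0.754484 -0.030700
A B DT P P -0.065670 0.894949 0.214100
A B DT OP1 O -0.004954 1.029203 0.200000
A B DT OP2 O -0.189190 0.871597 0.135900
A B DT O5' O 0.042683 0.782595 0.178800
A B DT C5' C 0.144413 0.750951 0.275600
A B DT C4' C 0.269509 0.701958 0.205300
A B DT O4' O 0.247769 0.562994 0.182300
A B DT C1' C 0.230777 0.533313 0.045200
A B DT N1 N 0.109812 0.446793 0.037000
A B DT C6 C -0.015786 0.501219 0.040000
A B DT C5 C -0.125491 0.424070 0.032700
A B DT C7 C -0.263553 0.482607 0.035800
A B DT C4 C -0.114078 0.280546 0.021400
A B DT O4 O -0.208637 0.201786 0.014100
A B DT N3 N 0.015935 0.234408 0.019100
A B DT C2 C 0.130404 0.311309 0.026500
A B DT O2 O 0.241436 0.261163 0.023700
A B DT C3' C 0.295084 0.760632 0.066500
A B DT C2' C 0.214838 0.667887 -0.024700
A B DT O3' O 0.432454 0.754390 0.030700
C A DC P P -0.065787 -0.894858 -0.214100
C A DC OP1 O -0.005067 -1.029215 -0.200000
C A DC OP2 O -0.189313 -0.871604 -0.135900
C A DC O5' O 0.042587 -0.782625 -0.178800
C A DC C5' C 0.144320 -0.750982 -0.275600
C A DC C4' C 0.269433 -0.701963 -0.205300
C A DC O4' O 0.247648 -0.563017 -0.182300
C A DC C1' C 0.230777 -0.533329 -0.045200
C A DC N1 N 0.109834 -0.446809 -0.037000
C A DC C6 C -0.015189 -0.500467 -0.039900
C A DC C5 C -0.125394 -0.421626 -0.032500
C A DC C4 C -0.103567 -0.280499 -0.021500
C A DC N4 N -0.206533 -0.197648 -0.013800
C A DC N3 N 0.019963 -0.228724 -0.018700
C A DC C2 C 0.128934 -0.309264 -0.026300
C A DC O2 O 0.244440 -0.265132 -0.024100
C A DC C3' C 0.294984 -0.760704 -0.066500
C A DC C2' C 0.214792 -0.667946 0.024700
C A DC O3' O 0.432386 -0.754484 -0.030700
C B DG P P -0.065670 0.894949 0.214100
C B DG OP1 O -0.004954 1.029203 0.200000
C B DG OP2 O -0.189190 0.871597 0.135900
C B DG O5' O 0.042683 0.782595 0.178800
C B DG C5' C 0.144413 0.750951 0.275600
C B DG C4' C 0.269509 0.701958 0.205300
C B DG O4' O 0.247769 0.562994 0.182300
C B DG C1' C 0.230777 0.533313 0.045200
C B DG N9 N 0.109812 0.446793 0.037000
C B DG C8 C -0.023167 0.482725 0.038400
C B DG N7 N -0.105843 0.381362 0.029500
C B DG C5 C -0.021716 0.270542 0.021600
C B DG C6 C -0.053213 0.132610 0.010300
C B DG O6 O -0.163494 0.078995 0.004700
C B DG N1 N 0.062830 0.053977 0.005300
C B DG C2 C 0.192075 0.102218 0.010600
C B DG N2 N 0.289089 0.010836 0.004300
C B DG N3 N 0.221399 0.231717 0.021200
C B DG C4 C 0.110091 0.309381 0.026100
C B DG C3' C 0.295084 0.760632 0.066500
C B DG C2' C 0.214838 0.667887 -0.024700
C B DG O3' O 0.432454 0.754390 0.030700
G A DG P P -0.065787 -0.894858 -0.214100
G A DG OP1 O -0.005067 -1.029215 -0.200000
G A DG OP2 O -0.189313 -0.871604 -0.135900
G A DG O5' O 0.042587 -0.782625 -0.178800
G A DG C5' C 0.144320 -0.750982 -0.275600
G A DG C4' C 0.269433 -0.701963 -0.205300
G A DG O4' O 0.247648 -0.563017 -0.182300
G A DG C1' C 0.230777 -0.533329 -0.045200
G A DG N9 N 0.109834 -0.446809 -0.037000
G A DG C8 C -0.023218 -0.482767 -0.038400
G A DG N7 N -0.105921 -0.381386 -0.029500
G A DG C5 C -0.021808 -0.270561 -0.021600
G A DG C6 C -0.053239 -0.132641 -0.010300
G A DG O6 O -0.163463 -0.079003 -0.004700
G A DG N1 N 0.062744 -0.053997 -0.005300
G A DG C2 C 0.192030 -0.102326 -0.010600
G A DG N2 N 0.289076 -0.010787 -0.004300
G A DG N3 N 0.221391 -0.231697 -0.021200
G A DG C4 C 0.110054 -0.309390 -0.026100
G A DG C3' C 0.294984 -0.760704 -0.066500
G A DG C2' C 0.214792 -0.667946 0.024700
G A DG O3' O 0.432386 -0.754484 -0.030700
G B DC P P -0.065670 0.894949 0.214100
G B DC OP1 O -0.004954 1.029203 0.200000
G B DC OP2 O -0.189190 0.871597 0.135900
G B DC O5' O 0.042683 0.782595 0.178800
G B DC C5' C 0.144413 0.750951 0.275600
G B DC C4' C 0.269509 0.701958 0.205300
G B DC O4' O 0.247769 0.562994 0.182300
G B DC C1' C 0.230777 0.533313 0.045200
G B DC N1 N 0.109812 0.446793 0.037000
G B DC C6 C -0.015095 0.500469 0.039900
G B DC C5 C -0.125395 0.421651 0.032500
G B DC C4 C -0.103476 0.280506 0.021500
G B DC N4 N -0.206555 0.197677 0.013800
G B DC N3 N 0.019981 0.228749 0.018700
G B DC C2 C 0.128935 0.309286 0.026300
G B DC O2 O 0.244456 0.265149 0.024100
G B DC C3' C 0.295084 0.760632 0.066500
G B DC C2' C 0.214838 0.667887 -0.024700
G B DC O3' O 0.432454 0.754390 0.030700
T A DT P P -0.065787 -0.894858 -0.214100
T A DT OP1 O -0.005067 -1.029215 -0.200000
T A DT OP2 O -0.189313 -0.871604 -0.135900
T A DT O5' O 0.042587 -0.782625 -0.178800
T A DT C5' C 0.144320 -0.750982 -0.275600
T A DT C4' C 0.269433 -0.701963 -0.205300
T A DT O4' O 0.247648 -0.563017 -0.182300
T A DT C1' C 0.230777 -0.533329 -0.045200
T A DT N1 N 0.109834 -0.446809 -0.037000
T A DT C6 C -0.015858 -0.501217 -0.040000
T A DT C5 C -0.125518 -0.424008 -0.032700
T A DT C7 C -0.263648 -0.482605 -0.035800
T A DT C4 C -0.114147 -0.280599 -0.021400
T A DT O4 O -0.208671 -0.201781 -0.014100
T A DT N3 N 0.015907 -0.234306 -0.019100
T A DT C2 C 0.130325 -0.311264 -0.026500
T A DT O2 O 0.241461 -0.261236 -0.023700
T A DT C3' C 0.294984 -0.760704 -0.066500
T A DT C2' C 0.214792 -0.667946 0.024700
T A DT O3' O 0.432386 -0.754484 -0.030700
T B DA P P -0.065670 0.894949 0.214100
T B DA OP1 O -0.004954 1.029203 0.200000
T B DA OP2 O -0.189190 0.871597 0.135900
T B DA O5' O 0.042683 0.782595 0.178800
T B DA C5' C 0.144413 0.750951 0.275600
T B DA C4' C 0.269509 0.701958 0.205300
T B DA O4' O 0.247769 0.562994 0.182300
T B DA C1' C 0.230777 0.533313 0.045200
T B DA N9 N 0.109812 0.446793 0.037000
T B DA C8 C -0.022932 0.483048 0.038500
T B DA N7 N -0.104946 0.382936 0.029600
T B DA C5 C -0.021901 0.272160 0.021700
T B DA C6 C -0.048163 0.134627 0.010500
T B DA N6 N -0.171958 0.083168 0.005100
T B DA N1 N 0.057545 0.051637 0.005100
T B DA C2 C 0.180157 0.103338 0.010500
T B DA N3 N 0.216857 0.229208 0.020900
T B DA C4 C 0.109039 0.310145 0.026200
T B DA C3' C 0.295084 0.760632 0.066500
T B DA C2' C 0.214838 0.667887 -0.024700
T B DA O3' O 0.432454 0.754390 0.030700
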