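# Synthetic reconstruction of the five CDC "Integrated Food Safety Centers of
# Excellence" regions. Hub states and per-region state counts follow the
# published description (Colorado: 10 states; Minnesota: 10 states; New York:
# 12 states + DC; Tennessee: 11 states + PR + VI; Washington: 7 states + Guam);
# the exact memberships are not published alongside it, so the assignment of
# non-hub states is an approximation by geography.
state,region
WA,Washington
OR,Washington
ID,Washington
AK,Washington
HI,Washington
CA,Washington
NV,Washington
GU,Washington
CO,Colorado
MT,Colorado
WY,Colorado
UT,Colorado
AZ,Colorado
NM,Colorado
ND,Colorado
SD,Colorado
NE,Colorado
KS,Colorado
MN,Minnesota
WI,Minnesota
MI,Minnesota
IL,Minnesota
IN,Minnesota
OH,Minnesota
IA,Minnesota
MO,Minnesota
TX,Minnesota
OK,Minnesota
NY,New York
NJ,New York
PA,New York
CT,New York
RI,New York
MA,New York
VT,New York
NH,New York
ME,New York
DE,New York
MD,New York
VA,New York
DC,New York
TN,Tennessee
KY,Tennessee
WV,Tennessee
NC,Tennessee
SC,Tennessee
GA,Tennessee
FL,Tennessee
AL,Tennessee
MS,Tennessee
LA,Tennessee
AR,Tennessee
PR,Tennessee
VI,Tennessee
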