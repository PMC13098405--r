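phone,class
p,occlusive
b,occlusive
t,occlusive
d,occlusive
k,occlusive
g,occlusive
f,fricative
v,fricative
s,fricative
z,fricative
S,fricative
Z,fricative
m,nasal
n,nasal
J,nasal
N,nasal
l,liquid
R,liquid
j,semivowel
w,semivowel
H,semivowel
a,oral_vowel
e,oral_vowel
E,oral_vowel
i,oral_vowel
o,oral_vowel
O,oral_vowel
u,oral_vowel
y,oral_vowel
2,oral_vowel
9,oral_vowel
@,oral_vowel
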