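[PAD]
[UNK]
[CLS]
[SEP]
.
,
(
)
/
;
:
-
1
2
3
4
5
a
adult
african
aged
aids
and
antipsychotic
arthritis
as
asian
atrial
bangladeshi
black
bmi
caribbean
chinese
chronic
class
classified
coronary
corticosteroid
diabetes
disease
dysfunction
erectile
erythematosus
ethnic
ethnicity
ex
extreme
family
fibrillation
group
has
heart
heavy
high
history
hiv
hypertension
illness
indian
indicating
is
kidney
light
low
lupus
mellitus
mental
middle
migraine
moderate
nonsmoker
normal
obesity
of
old
older
or
other
overweight
pakistani
patient
pre
preobesity
rheumatoid
risk
severe
smoker
stage
stratified
systemic
the
treated
type
underweight
weight
white
with
young
b
c
d
e
f
g
h
i
j
k
l
m
n
o
p
q
r
s
t
u
v
w
x
y
z
0
6
7
8
9
##a
##b
##c
##d
##e
##f
##g
##h
##i
##j
##k
##l
##m
##n
##o
##p
##q
##r
##s
##t
##u
##v
##w
##x
##y
##z
##0
##1
##2
##3
##4
##5
##6
##7
##8
##9
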