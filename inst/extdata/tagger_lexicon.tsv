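# word<TAB>tag lexicon for the deterministic rule tagger (lowercase forms)
the	DT
a	DT
an	DT
and	CC
or	CC
but	CC
of	IN
in	IN
on	IN
at	IN
with	IN
for	IN
by	IN
from	IN
as	IN
per	IN
after	IN
before	IN
around	IN
against	IN
within	IN
without	IN
during	IN
under	IN
over	IN
between	IN
to	TO
no	DT
not	RB
is	VBZ
was	VBD
are	VBP
were	VBD
be	VB
been	VBN
being	VBG
has	VBZ
have	VBP
had	VBD
can	MD
will	MD
would	MD
should	MD
could	MD
may	MD
might	MD
must	MD
do	VBP
does	VBZ
did	VBD
he	PRP
she	PRP
it	PRP
they	PRP
them	PRP
we	PRP
her	PRP
his	PRP
their	PRP
this	DT
that	DT
these	DT
those	DT
who	WP
what	WP
when	WRB
where	WRB
which	WDT
while	IN
white	JJ
black	JJ
blood	NN
patient	NN
patients	NNS
started	VBD
follow	VB
physical	JJ
assessment	NN
renal	JJ
imaging	NN
plan	NN
care	NN
last	JJ
next	JJ
first	JJ
symptoms	NNS
notable	JJ
left	VBD
clinic	NN
page	VB
ssn	NN
results	NNS
result	NN
portal	NN
unique	JJ
mrn	NN
billing	NN
pacemaker	NN
consent	NN
countersigned	VBD
covering	VBG
discharge	NN
transferred	VBN
seen	VBN
presents	VBZ
fluid	NN
found	VBD
old	JJ
years	NNS
age	NN
daily	RB
twice	RB
stable	JJ
regular	JJ
clear	JJ
normal	JJ
acute	JJ
soft	JJ
new	JJ
note	NN
notes	NNS
pain	NN
chest	NN
heart	NN
rate	NN
pressure	NN
lungs	NNS
exam	NN
abdomen	NN
fever	NN
nausea	NN
vomiting	NN
culture	NN
site	NN
wound	NN
lab	NN
labs	NNS
medications	NNS
dose	NN
continue	VB
denies	VBZ
reviewed	VBN
discussed	VBN
verified	VBN
confirmed	VBN
updated	VBN
scheduled	VBN
arranged	VBN
located	VBN
logged	VBN
signed	VBN
reached	VBN
interrogated	VBN
began	VBD
lives	VBZ
returned	VBD
call	VB
email	NN
fax	NN
records	NNS
license	NN
account	NN
serial	NN
battery	NN
staff	NN
today	NN
yesterday	NN
overnight	RB
independently	RB
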