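the
a
an
and
or
but
not
no
yes
of
in
on
at
with
for
to
by
from
as
per
after
before
around
against
within
without
about
above
below
between
during
under
over
into
onto
through
is
was
are
were
be
been
being
has
have
had
can
will
would
should
could
may
might
must
do
does
did
done
he
she
it
they
them
their
her
his
him
its
this
that
these
those
we
us
our
you
your
i
me
my
who
what
when
where
which
while
how
why
all
any
each
every
some
most
more
less
many
much
few
several
both
other
another
same
such
only
also
very
quite
well
now
then
today
yesterday
tomorrow
here
there
again
once
daily
twice
weekly
monthly
often
rarely
never
always
currently
recently
still
yet
soon
later
early
late
new
old
young
good
bad
high
low
large
small
long
short
left
right
first
second
third
last
next
prior
previous
recent
current
normal
abnormal
stable
unstable
mild
moderate
severe
acute
chronic
regular
irregular
clear
soft
hard
warm
cold
dry
wet
white
black
red
blue
green
yellow
pale
pink
price
bell
berry
stone
walks
walk
walking
knee
knees
home
child
children
family
wife
husband
mother
father
sister
brother
son
daughter
patient
patients
person
people
man
woman
men
women
doctor
nurse
physician
provider
staff
team
visit
visits
appointment
clinic
hospital
office
room
bed
bedside
unit
ward
floor
center
care
health
medical
history
review
exam
examination
assessment
plan
note
notes
chart
record
records
result
results
report
reports
test
tests
level
levels
value
values
range
limits
function
status
condition
state
course
follow
followup
continue
continued
start
started
stop
stopped
hold
held
increase
increased
decrease
decreased
change
changed
improve
improved
worsen
worsening
resolve
resolved
persist
persistent
present
presents
presented
presenting
return
returned
admit
admitted
discharge
discharged
transfer
transferred
refer
referred
schedule
scheduled
arrange
arranged
order
ordered
check
checked
monitor
monitored
measure
measured
observe
observed
note
noted
find
found
findings
show
showed
reveal
revealed
report
reported
deny
denies
denied
complain
complains
complaint
describe
describes
state
states
stated
feel
feels
felt
appear
appears
appeared
seem
seems
look
looks
take
takes
taking
taken
give
given
giving
use
uses
using
used
need
needs
needed
require
requires
required
receive
received
tolerate
tolerated
respond
responded
response
discuss
discussed
discussion
explain
explained
understand
understanding
verbalize
verbalized
agree
agreed
consent
signed
sign
signs
symptom
symptoms
pain
ache
fever
chills
cough
nausea
vomiting
diarrhea
constipation
fatigue
weakness
dizziness
headache
rash
swelling
edema
bleeding
bruising
numbness
tingling
shortness
breath
breathing
chest
heart
lung
lungs
head
neck
back
arm
arms
leg
legs
foot
feet
hand
hands
eye
eyes
ear
ears
nose
throat
mouth
skin
bone
joint
joints
muscle
muscles
abdomen
stomach
liver
kidney
kidneys
bladder
bowel
blood
urine
fluid
fluids
pressure
rate
rhythm
pulse
temperature
weight
height
oxygen
glucose
sugar
sodium
potassium
calcium
protein
cell
cells
count
culture
sample
specimen
lab
labs
imaging
scan
film
study
studies
medication
medications
medicine
drug
drugs
dose
doses
dosage
tablet
tablets
capsule
pill
pills
injection
infusion
therapy
treatment
treatments
procedure
procedures
surgery
surgical
operation
wound
site
incision
dressing
suture
bandage
brace
cast
splint
device
monitor
machine
tube
line
catheter
pump
serial
battery
adequate
intact
alert
oriented
awake
asleep
comfortable
distress
distressed
unremarkable
remarkable
significant
negative
positive
within
without
auscultation
palpation
inspection
tender
nontender
distended
nondistended
supple
benign
routine
urgent
emergent
elective
outpatient
inpatient
admission
registration
wristband
billing
account
insurance
coverage
covering
attending
resident
intern
fellow
specialist
consult
consultation
referral
management
ongoing
independently
cognition
notable
verified
confirmed
updated
reviewed
available
arranged
located
reached
scheduling
message
contact
prefers
email
portal
access
logged
identifier
unique
requests
overnight
page
fax
registration
presence
countersigned
interrogated
pacemaker
earlier
began
worsening
rheumatology
cardiology
neurology
oncology
radiology
pathology
psychiatry
pediatrics
geriatrics
surgery
anesthesia
pharmacy
nursing
therapy
years
months
weeks
days
hours
minutes
year
month
week
day
hour
minute
time
times
age
ages
date
dates
number
numbers
amount
total
none
several
approximately
roughly
nearly
almost
exactly
likely
unlikely
possible
probable
definite
uncertain
unknown
license
file
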