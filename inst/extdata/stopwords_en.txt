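# Standard English stop-list (one word per line). Entries are stemmed on
# load, so grammatical variants are excluded too. Words on the retained
# override list (stopwords_retained.txt) survive no matter what appears here.
a
about
above
after
again
against
all
am
an
and
any
are
as
at
back
be
because
been
before
being
below
between
both
but
by
came
can
come
could
did
do
does
doing
down
during
each
few
for
from
further
get
got
had
has
have
having
he
her
here
hers
herself
him
himself
his
how
i
if
in
into
is
it
its
itself
just
me
more
most
my
myself
no
nor
not
now
of
off
on
once
only
onto
or
other
our
ours
ourselves
out
over
own
per
saw
same
she
should
so
some
such
than
that
the
their
theirs
them
themselves
then
there
these
they
this
those
through
to
too
under
until
up
upon
very
was
we
went
were
what
when
where
which
while
whilst
who
whom
why
will
with
would
you
your
yours
yourself
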