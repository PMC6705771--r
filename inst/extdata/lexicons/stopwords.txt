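a
an
the
is
are
was
were
be
been
being
am
do
does
did
done
has
have
had
having
will
would
shall
should
can
could
may
might
must
of
for
to
in
on
at
by
with
from
as
into
onto
over
under
between
among
through
during
before
after
above
below
up
down
out
off
again
further
once
here
there
where
when
why
how
what
which
who
whom
whose
that
this
these
those
it
its
itself
they
them
their
theirs
themselves
we
us
our
ours
ourselves
you
your
yours
he
him
his
she
her
hers
i
me
my
mine
and
or
but
nor
so
yet
if
than
then
because
while
until
although
though
whereas
not
no
nor
only
own
same
such
both
each
few
more
most
other
some
any
all
very
too
also
just
about
against
per
via
within
without
upon
toward
towards
s
et
al
e.g
i.e
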